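#' Basis truncation for the Zernike3D expansion
#'
#' Defines the truncation of the Zernike3D basis: `N` bounds the combined
#' radial degree, `L` the angular degree, and `p` is the inner-product /
#' dimensionality parameter of the generalized Zernike polynomials (`p = 1`
#' for 3D volumes). The admissible index triples `(l, n, m)` satisfy
#' `l <= L`, `2n + l <= N`, `-l <= m <= l`; with the defaults `N = 3, L = 2`
#' this yields 13 triples, i.e. 39 scalar components over the three spatial
#' directions.
#'
#' @param N maximum combined radial degree (non-negative integer).
#' @param L maximum angular degree (non-negative integer).
#' @param p inner-product parameter (non-negative; 1 for volumes).
#' @return an object of class `basis_spec`.
#' @seealso [zernike_indices()]
#' @export
basis_spec <- function(N = 3L, L = 2L, p = 1) {
  N <- as.integer(N); L <- as.integer(L)
  if (is.na(N) || N < 0L) stop("N must be a non-negative integer")
  if (is.na(L) || L < 0L) stop("L must be a non-negative integer")
  if (!is.finite(p) || p < 0) stop("p must be non-negative")
  structure(list(N = N, L = L, p = p), class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  k <- nrow(zernike_indices(x))
  cat(sprintf("Zernike3D basis spec: N = %d, L = %d, p = %g (%d indices, %d components)\n",
              x$N, x$L, x$p, k, 3L * k))
  invisible(x)
}

#' Enumerate the admissible Zernike3D index triples
#'
#' Lists every `(l, n, m)` with `0 <= l <= L`, `n >= 0`, `2n + l <= N` and
#' `-l <= m <= l`, in lexicographic order of `(l, n, m)`. The ordering is
#' the canonical component order used by coefficient tables, flattened
#' coefficient vectors and landscape columns.
#'
#' @param spec a [basis_spec()].
#' @return a data.frame with integer columns `l`, `n`, `m`.
#' @export
zernike_indices <- function(spec) {
  stopifnot(inherits(spec, "basis_spec"))
  rows <- list()
  for (l in 0:spec$L) {
    nmax <- (spec$N - l) %/% 2L
    if (nmax < 0L) next
    for (n in 0:nmax) for (m in (-l):l)
      rows[[length(rows) + 1L]] <- c(l, n, m)
  }
  idx <- do.call(rbind, rows)
  data.frame(l = as.integer(idx[, 1]), n = as.integer(idx[, 2]),
             m = as.integer(idx[, 3]))
}

# Jacobi polynomial P_n^(a,b)(x), three-term recurrence, vectorized in x.
jacobi_poly <- function(n, a, b, x) {
  if (n == 0L) return(rep(1, length(x)))
  p0 <- rep(1, length(x))
  p1 <- 0.5 * (a - b + (a + b + 2) * x)
  if (n == 1L) return(p1)
  for (k in 2:n) {
    c1 <- 2 * k * (k + a + b) * (2 * k + a + b - 2)
    c2 <- (2 * k + a + b - 1) * (a^2 - b^2)
    c3 <- (2 * k + a + b - 2) * (2 * k + a + b - 1) * (2 * k + a + b)
    c4 <- 2 * (k + a - 1) * (k + b - 1) * (2 * k + a + b)
    p2 <- ((c2 + c3 * x) * p1 - c4 * p0) / c1
    p0 <- p1; p1 <- p2
  }
  p1
}

# Associated Legendre P_l^m(x), m >= 0, WITHOUT the Condon-Shortley phase
# (the (-1)^m factor lives in the spherical-harmonic definition instead, so
# the phase is not double-counted). Vectorized in x.
assoc_legendre <- function(l, m, x) {
  stopifnot(m >= 0L, m <= l)
  somx2 <- sqrt(pmax(0, 1 - x^2))
  pmm <- rep(1, length(x))
  if (m > 0) {
    fact <- 1
    for (i in seq_len(m)) {
      pmm <- pmm * fact * somx2
      fact <- fact + 2
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1L) return(pmmp1)
  pll <- pmmp1
  for (ll in (m + 2L):l) {
    pll <- (x * (2 * ll - 1) * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1; pmmp1 <- pll
  }
  pll
}

#' Normalized generalized Zernike radial polynomial
#'
#' Evaluates the normalized radial component
#' \eqn{\bar R^p_{l,n}(x) = \sqrt2 \sqrt{2n + l + p/2 + 1}\, R^p_{l,n}(x)}
#' with \eqn{R^p_{l,n}(x) = x^l P_n^{(0,\, l + p/2)}(2x^2 - 1)} (Jacobi
#' polynomial form). For `p = 1` the normalization gives unit norm in
#' \eqn{L^2([0,1], x^2\,dx)}.
#'
#' @param l angular degree, `n` radial index (both non-negative integers).
#' @param n radial index.
#' @param x radius in `[0, 1]` (vectorized).
#' @param p inner-product parameter (default 1).
#' @return numeric vector of radial values.
#' @export
zernike_radial <- function(l, n, x, p = 1) {
  if (l < 0L || n < 0L) stop("l and n must be non-negative")
  if (any(x < 0 | x > 1)) stop("radial argument outside [0, 1]")
  norm <- sqrt(2) * sqrt(2 * n + l + p / 2 + 1)
  norm * x^l * jacobi_poly(n, 0, l + p / 2, 2 * x^2 - 1)
}

#' Real spherical harmonic
#'
#' Evaluates the real spherical harmonic
#' \deqn{y_l^m(\theta,\phi) = (-1)^m \sqrt{\frac{2l+1}{4\pi}
#'   \frac{(l-|m|)!}{(l+|m|)!}} P_l^{|m|}(\cos\theta)\times
#'   \{1,\ \sqrt2\cos m\phi,\ \sqrt2\sin|m|\phi\}}
#' for `m = 0`, `m > 0`, `m < 0` respectively, with the associated Legendre
#' function taken without the Condon-Shortley phase. `theta` is the polar
#' angle from +Z, `phi` the azimuth from +X.
#'
#' @param l degree, `m` order with `|m| <= l`.
#' @param m azimuthal order.
#' @param theta polar angle(s) in `[0, pi]`.
#' @param phi azimuthal angle(s).
#' @return numeric vector of harmonic values.
#' @export
sph_harm_real <- function(l, m, theta, phi) {
  if (abs(m) > l) stop("|m| must not exceed l")
  am <- abs(m)
  norm <- (-1)^m * sqrt((2 * l + 1) / (4 * pi) *
                          factorial(l - am) / factorial(l + am))
  plm <- assoc_legendre(l, am, cos(theta))
  if (m == 0) norm * plm
  else if (m > 0) norm * plm * sqrt(2) * cos(m * phi)
  else norm * plm * sqrt(2) * sin(am * phi)
}

#' Zernike3D basis function on the unit ball
#'
#' Evaluates \eqn{Z_{l,n,m}(r) = \bar R^1_{l,n}(\|r\|)\, y_l^m(\theta,\phi)}
#' at Cartesian points of the unit ball; points with `||r|| > 1` evaluate to
#' zero (the basis is defined over the unit ball only).
#'
#' @param l,n,m index triple.
#' @param points numeric matrix (npts x 3) of Cartesian coordinates.
#' @param p inner-product parameter (default 1).
#' @return numeric vector of length `nrow(points)`.
#' @export
zernike_basis <- function(l, n, m, points, p = 1) {
  points <- rbind(points)
  r <- sqrt(rowSums(points^2))
  out <- numeric(length(r))
  ok <- r <= 1
  if (!any(ok)) return(out)
  rr <- r[ok]
  ct <- ifelse(rr > 0, points[ok, 3] / rr, 1)
  ct <- pmin(1, pmax(-1, ct))
  theta <- acos(ct)
  phi <- atan2(points[ok, 2], points[ok, 1])
  out[ok] <- zernike_radial(l, n, rr, p) * sph_harm_real(l, m, theta, phi)
  out
}

#' Basis design matrix at a set of points
#'
#' Evaluates every basis function of a truncation at a set of Cartesian
#' unit-ball points, returning the (npts x K) matrix whose columns follow
#' [zernike_indices()] order. This matrix is the workhorse shared by field
#' evaluation, volume warping and coefficient estimation.
#'
#' @param spec a [basis_spec()].
#' @param points numeric matrix (npts x 3).
#' @return numeric matrix (npts x K).
#' @export
basis_matrix <- function(spec, points) {
  idx <- zernike_indices(spec)
  points <- rbind(points)
  npts <- nrow(points)
  r <- sqrt(rowSums(points^2))
  ok <- r <= 1
  Z <- matrix(0, npts, nrow(idx))
  if (any(ok)) {
    rr <- r[ok]
    ct <- ifelse(rr > 0, points[ok, 3] / rr, 1)
    ct <- pmin(1, pmax(-1, ct))
    theta <- acos(ct)
    phi <- atan2(points[ok, 2], points[ok, 1])
    for (i in seq_len(nrow(idx))) {
      Z[ok, i] <- zernike_radial(idx$l[i], idx$n[i], rr, spec$p) *
        sph_harm_real(idx$l[i], idx$m[i], theta, phi)
    }
  }
  Z
}
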