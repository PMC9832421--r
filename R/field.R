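#' Zernike3D coefficient set
#'
#' The central object of the method: one 3-vector of expansion weights
#' `(alpha_x, alpha_y, alpha_z)` per admissible basis index, plus the
#' physical radius (Angstrom) that maps the unit ball onto the volume box.
#' Coefficients are dimensionless displacements in unit-ball units; the
#' physical displacement at a point is `scale_radius * g(r)`.
#'
#' Sign convention (fixed package-wide): coefficients are the displacement
#' added to the *sampling* point of a gather warp, i.e.
#' `warp_volume(v, c)` produces `out(r) = v(r + g(r))`. Under this
#' convention density content moves by approximately `-g`; use
#' [negate_coefficients()] when a push-forward displacement (e.g. of atoms
#' tracking the density) is needed.
#'
#' @param spec a [basis_spec()].
#' @param alphas numeric K x 3 matrix (columns x, y, z) in
#'   [zernike_indices()] order, or NULL for all zeros.
#' @param scale_radius physical unit-ball radius in Angstrom.
#' @return an object of class `coefficient_set`.
#' @export
coefficient_set <- function(spec, alphas = NULL, scale_radius) {
  stopifnot(inherits(spec, "basis_spec"))
  k <- nrow(zernike_indices(spec))
  if (is.null(alphas)) alphas <- matrix(0, k, 3)
  alphas <- as.matrix(alphas)
  if (nrow(alphas) != k || ncol(alphas) != 3L)
    stop(sprintf("alphas must be %d x 3 for this basis spec", k))
  if (!all(is.finite(alphas))) stop("coefficients must be finite")
  if (!is.finite(scale_radius) || scale_radius <= 0)
    stop("scale_radius must be positive")
  dimnames(alphas) <- list(NULL, c("x", "y", "z"))
  structure(list(spec = spec, alphas = alphas, scale_radius = scale_radius),
            class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat(sprintf(
    "coefficient_set: N=%d L=%d (%d components), scale_radius = %.4g A, |alpha| = %.4g\n",
    x$spec$N, x$spec$L, 3L * nrow(x$alphas), x$scale_radius,
    sqrt(sum(x$alphas^2))))
  invisible(x)
}

#' Flatten a coefficient set to a direction-major vector
#'
#' All x components first (in index order), then y, then z — the coordinate
#' ordering used by the Powell optimizer.
#'
#' @param c a [coefficient_set()].
#' @return numeric vector of length 3K.
#' @export
coeffs_flatten <- function(c) as.vector(c$alphas)

coeffs_unflatten <- function(x, spec, scale_radius) {
  coefficient_set(spec, matrix(x, ncol = 3), scale_radius)
}

#' Negate a coefficient set
#'
#' Convenience helper for switching between the gather-warp convention
#' (sampling-point displacement) and the push-forward displacement of
#' material points; see [coefficient_set()].
#'
#' @param c a [coefficient_set()].
#' @return the coefficient set with all components negated.
#' @export
negate_coefficients <- function(c) {
  c$alphas <- -c$alphas
  c
}

#' Add two coefficient sets
#'
#' @param a,b coefficient sets sharing basis spec and scale.
#' @return their sum (fields add linearly).
#' @export
add_coefficients <- function(a, b) {
  stopifnot(identical(a$spec, b$spec),
            isTRUE(all.equal(a$scale_radius, b$scale_radius)))
  a$alphas <- a$alphas + b$alphas
  a
}

#' Scale the components of a coefficient set in place
#'
#' Multiplies the expansion weights by a scalar without touching the
#' physical scale; the field scales linearly.
#'
#' @param c a [coefficient_set()].
#' @param s scalar.
#' @return scaled coefficient set.
#' @export
scale_coefficients <- function(c, s) {
  c$alphas <- c$alphas * s
  c
}

#' Evaluate the deformation field
#'
#' Computes `g(r) = sum_lnm alpha_lnm Z_lnm(r)` at Cartesian unit-ball
#' points; zero outside the unit ball. The result is dimensionless
#' (unit-ball units); multiply by `c$scale_radius` for Angstrom.
#'
#' @param c a [coefficient_set()].
#' @param points numeric matrix (npts x 3) in unit-ball coordinates.
#' @return numeric matrix (npts x 3) of displacements.
#' @export
evaluate_field <- function(c, points) {
  Z <- basis_matrix(c$spec, points)
  Z %*% c$alphas
}

#' Warp a volume with a deformation field (gather semantics)
#'
#' Produces `out(r) = v(r + g(r))` by trilinear interpolation; samples
#' falling outside the box read zero, voxels outside the unit ball are
#' untouched (the field vanishes there). An all-zero coefficient set
#' returns the input unchanged.
#'
#' @param v a [volume_grid()].
#' @param c a [coefficient_set()]; its `scale_radius` fixes the physical
#'   extent of the unit ball inside the box.
#' @return warped [volume_grid()].
#' @export
warp_volume <- function(v, c) {
  stopifnot(inherits(v, "volume_grid"), inherits(c, "coefficient_set"))
  b <- ball_voxels(vol_box(v))
  Z <- basis_matrix(c$spec, b$unit)
  rvox <- c$scale_radius / v$voxel_size
  volume_grid(cpp_warp_coeffs(v$values, b$ijk, Z, c$alphas, rvox),
              v$voxel_size)
}

#' Warp an atomic model with a deformation field
#'
#' Each atom at physical position `x` (unit-ball coordinates
#' `u = x / scale_radius`) moves to `scale_radius * (u + g(u))`. Atoms
#' outside the unit ball are left in place and counted in a warning.
#'
#' @param mdl an [atomic_model()].
#' @param c a [coefficient_set()].
#' @return the deformed model.
#' @export
warp_model <- function(mdl, c) {
  stopifnot(inherits(mdl, "atomic_model"))
  pos <- as.matrix(mdl$atoms[, c("x", "y", "z")])
  u <- pos / c$scale_radius
  inside <- sqrt(rowSums(u^2)) <= 1
  if (any(!inside))
    warning(sprintf("%d atom(s) outside the unit ball left unmoved",
                    sum(!inside)))
  if (any(inside)) {
    g <- evaluate_field(c, u[inside, , drop = FALSE])
    pos[inside, ] <- (u[inside, , drop = FALSE] + g) * c$scale_radius
  }
  mdl$atoms$x <- pos[, 1]; mdl$atoms$y <- pos[, 2]; mdl$atoms$z <- pos[, 3]
  mdl
}

# Real-spherical-harmonic rotation matrix D for degree l and rotation A,
# defined by y_l^m(A^-1 u) = sum_m' D[m, m'] y_l^m'(u). Obtained by solving
# the exact linear relation on a fixed Fibonacci-sphere point set; the
# system is overdetermined and consistent, so the least-squares solution is
# exact to machine precision.
sh_rotation_matrix <- function(l, A) {
  if (l == 0L) return(matrix(1, 1, 1))
  q <- max(4L * (2L * l + 1L), 24L)
  U <- fibonacci_sphere(q)
  Urot <- U %*% A   # rows are A^T u = A^-1 u
  ms <- (-l):l
  Y <- sapply(ms, function(m) {
    sph_harm_real(l, m, acos(pmin(1, pmax(-1, U[, 3]))),
                  atan2(U[, 2], U[, 1]))
  })
  Yrot <- sapply(ms, function(m) {
    sph_harm_real(l, m, acos(pmin(1, pmax(-1, Urot[, 3]))),
                  atan2(Urot[, 2], Urot[, 1]))
  })
  t(qr.solve(Y, Yrot))
}

fibonacci_sphere <- function(q) {
  i <- seq_len(q) - 0.5
  z <- 1 - 2 * i / q
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(q) - 1)
  cbind(r * cos(th), r * sin(th), z)
}

check_rotation <- function(A) {
  A <- as.matrix(A)
  if (!all(dim(A) == c(3, 3)) ||
      max(abs(crossprod(A) - diag(3))) > 1e-8 ||
      abs(det(A) - 1) > 1e-8)
    stop("A must be a proper rotation matrix (orthogonal, det +1)")
  A
}

#' Rotate a Zernike3D coefficient set
#'
#' The basis is closed under rotations in continuous space: there is a
#' coefficient set `c'` with `g'(r) = A g(A^-1 r)` for every `r`. It is
#' obtained by (i) rotating each per-index 3-vector by `A` and (ii) mixing
#' the `m` components within each `(l, n)` block by the real
#' spherical-harmonic rotation matrix of `A`.
#'
#' @param c a [coefficient_set()].
#' @param A 3x3 proper rotation matrix.
#' @return the rotated coefficient set.
#' @export
rotate_coefficients <- function(c, A) {
  A <- check_rotation(A)
  idx <- zernike_indices(c$spec)
  out <- c$alphas %*% t(A)   # rotate the vector parts
  for (l in unique(idx$l)) {
    D <- sh_rotation_matrix(l, A)
    for (n in unique(idx$n[idx$l == l])) {
      rows <- which(idx$l == l & idx$n == n)
      out[rows, ] <- t(D) %*% out[rows, , drop = FALSE]
    }
  }
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  c$alphas <- out
  c
}

# Proper rotation taking unit vector d onto +Z (Rodrigues construction).
rotation_to_z <- function(d) {
  d <- d / sqrt(sum(d^2))
  z <- c(0, 0, 1)
  v <- c(d[2] * 1 - d[3] * 0, d[3] * 0 - d[1] * 1, d[1] * 0 - d[2] * 0)
  # v = d x z
  s <- sqrt(sum(v^2))
  cth <- sum(d * z)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # 180 degrees about x
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

#' Cancel the field component along a projection direction
#'
#' The deformation along a particle's viewing axis is unobservable from
#' that single image. This removes it by the rotation route: rotate the
#' coefficients by the rotation taking `d` to +Z, zero every z component in
#' the rotated frame, and rotate back. The result satisfies
#' `g(r) . d = 0` everywhere while the components orthogonal to `d` are
#' preserved; the operation is idempotent and never increases the
#' deformation magnitude.
#'
#' @param c a [coefficient_set()].
#' @param d 3-vector projection direction (need not be normalized, but must
#'   be nonzero).
#' @return the projection-consistent coefficient set.
#' @export
cancel_projection_component <- function(c, d) {
  nd <- sqrt(sum(d^2))
  if (!is.finite(nd) || nd == 0) stop("projection direction must be nonzero")
  A <- rotation_to_z(d / nd)
  cr <- rotate_coefficients(c, A)
  cr$alphas[, 3] <- 0
  rotate_coefficients(cr, t(A))
}

#' Move a coefficient set to a different spatial scale
#'
#' When the grid underlying a coefficient set is rescaled by a factor `k`
#' (e.g. coefficients expressed against a downsampled map whose coordinates
#' shrink by `k`), the coefficients carry the same factor:
#' `alpha_o = k * alpha_d`. Every component and the physical unit-ball
#' radius are multiplied by `k`.
#'
#' @param c a [coefficient_set()].
#' @param k positive scale factor.
#' @return the rescaled coefficient set.
#' @export
rescale_coefficients <- function(c, k) {
  if (!is.finite(k) || k <= 0) stop("k must be positive")
  c$alphas <- c$alphas * k
  c$scale_radius <- c$scale_radius * k
  c
}

#' Mean deformation magnitude in Angstrom
#'
#' The mean over masked voxels (or over the whole unit ball when no mask is
#' given) of the physical displacement modulus
#' `scale_radius * ||g(r)||`. Positively homogeneous of degree one in the
#' coefficients; the quantity used to colour conformational landscapes.
#'
#' @param c a [coefficient_set()].
#' @param mask optional [volume_grid()]; voxels with positive value are
#'   averaged over (use e.g. `reference > 0.01 * max` to restrict to the
#'   molecule).
#' @param grid_n quadrature grid used when no mask is given (default 32).
#' @return mean displacement in Angstrom.
#' @export
deformation_magnitude <- function(c, mask = NULL, grid_n = 32L) {
  if (is.null(mask)) {
    pts <- ball_voxels(grid_n)$unit
  } else {
    stopifnot(inherits(mask, "volume_grid"))
    n <- vol_box(mask)
    c0 <- floor(n / 2)
    sel <- which(mask$values > 0)
    if (length(sel) == 0) stop("mask selects no voxels")
    ijk <- arrayInd(sel, dim(mask$values)) - 1L
    pts <- (ijk - c0) / (n / 2)
  }
  g <- evaluate_field(c, pts)
  mean(sqrt(rowSums(g^2))) * c$scale_radius
}

#' Molecular mask from a reference map
#'
#' Voxels where the reference exceeds a fraction of its maximum — the
#' default region over which deformation magnitudes are averaged, so that
#' the statistic refers to the molecule rather than empty solvent.
#'
#' @param v a [volume_grid()].
#' @param threshold fraction of the maximum (default 0.01).
#' @return a binary [volume_grid()] mask.
#' @export
molecular_mask <- function(v, threshold = 0.01) {
  volume_grid((v$values > threshold * max(v$values)) * 1, v$voxel_size)
}

# --- coefficient table text format ------------------------------------------

#' Write a coefficient table
#'
#' Versioned plain-text format: line 1 `zflex-coeffs v1`; line 2
#' `N L p scale_radius` (Angstrom); then one row per basis index
#' `l n m ax ay az` in [zernike_indices()] order.
#'
#' @param coeffs a [coefficient_set()] or list of them (rows concatenated
#'   as repeated blocks of K index rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coeffs <- function(coeffs, path) {
  if (inherits(coeffs, "coefficient_set")) coeffs <- list(coeffs)
  spec <- coeffs[[1]]$spec
  idx <- zernike_indices(spec)
  lines <- c("zflex-coeffs v1",
             sprintf("%d %d %.17g %.17g", spec$N, spec$L, spec$p,
                     coeffs[[1]]$scale_radius))
  for (cs in coeffs) {
    stopifnot(identical(cs$spec, spec))
    lines <- c(lines, sprintf("%d %d %d %.17g %.17g %.17g",
                              idx$l, idx$n, idx$m,
                              cs$alphas[, 1], cs$alphas[, 2], cs$alphas[, 3]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a coefficient table
#'
#' @param path file written by [write_coeffs()].
#' @return a list of [coefficient_set()] (length one for a single set).
#' @export
read_coeffs <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "zflex-coeffs v1")
    stop("not a zflex-coeffs v1 file")
  hdr <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
  spec <- basis_spec(hdr[1], hdr[2], hdr[3])
  scale_radius <- hdr[4]
  idx <- zernike_indices(spec)
  k <- nrow(idx)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) %% k != 0)
    stop(sprintf("coefficient row count %d is not a multiple of the %d basis indices",
                 length(body), k))
  vals <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  nset <- length(body) %/% k
  out <- vector("list", nset)
  for (s in seq_len(nset)) {
    block <- vals[((s - 1) * k + 1):(s * k), , drop = FALSE]
    if (!all(block[, 1] == idx$l & block[, 2] == idx$n & block[, 3] == idx$m))
      stop("index rows do not match the canonical enumeration order")
    out[[s]] <- coefficient_set(spec, block[, 4:6, drop = FALSE], scale_radius)
  }
  out
}
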