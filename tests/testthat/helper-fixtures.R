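# Shared fixtures built in code: no data files.

tiny_phantom <- local({
  cache <- list()
  function(box = 32) {
    key <- as.character(box)
    if (is.null(cache[[key]]))
      cache[[key]] <<- make_phantom(phantom_spec(box = box, voxel_size = 1.5))
    cache[[key]]
  }
})

random_rotation <- function() {
  q <- qr(matrix(rnorm(9), 3))
  A <- qr.Q(q)
  if (det(A) < 0) A[, 1] <- -A[, 1]
  A
}

random_coeffs <- function(spec, scale_radius, sd = 0.02) {
  k <- nrow(zernike_indices(spec))
  coefficient_set(spec, matrix(rnorm(3 * k, sd = sd), ncol = 3),
                  scale_radius)
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Random interior points of the unit ball.
ball_points <- function(n, rmax = 0.98) {
  p <- matrix(rnorm(3 * n), ncol = 3)
  r <- runif(n)^(1 / 3) * rmax
  p * (r / sqrt(rowSums(p^2)))
}

rel_rmse <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))

# Product Gauss-Legendre (radius, polar) x uniform (azimuth) quadrature on
# the unit ball, with weights including the r^2 sin(theta) Jacobian.
# Spectrally accurate for smooth integrands; independent of any voxel grid.
ball_quadrature <- function(nr = 48, nt = 32, np = 64) {
  gr <- pracma::gaussLegendre(nr, 0, 1)
  gc <- pracma::gaussLegendre(nt, -1, 1)
  phi <- (seq_len(np) - 1) * 2 * pi / np
  grid <- expand.grid(ir = seq_len(nr), ic = seq_len(nt), ip = seq_len(np))
  r <- gr$x[grid$ir]
  ct <- gc$x[grid$ic]
  st <- sqrt(pmax(0, 1 - ct^2))
  pts <- cbind(r * st * cos(phi[grid$ip]), r * st * sin(phi[grid$ip]),
               r * ct)
  w <- gr$w[grid$ir] * r^2 * gc$w[grid$ic] * (2 * pi / np)
  list(points = pts, weights = w)
}
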