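#' Options for coefficient estimation
#'
#' @param lambda1 weight of the deformation penalty subtracted from the
#'   correlation objective (recommended range 0.001-0.01; default 0.005).
#' @param max_sweeps maximum number of full Powell sweeps (default 5).
#' @param tol absolute convergence tolerance on the objective (default 1e-4).
#' @param cancel_projection cancel the field component along the particle's
#'   viewing direction after every sweep and on the final result
#'   (default TRUE; ignored in volume-to-volume mode).
#' @param line_interval half-width of the Powell line-search bracket in
#'   coefficient units (default 0.15, i.e. 15 percent of the unit-ball
#'   radius).
#' @param line_tol line-search tolerance in coefficient units.
#' @param lp_frac low-pass cutoff as a fraction of the working box's
#'   Nyquist frequency, applied identically to the particle and to the
#'   model projection before correlating (raised-cosine edge); the default
#'   0.4 corresponds to filtering at 2.5 times the Nyquist resolution, the
#'   standard practice of band-limiting noisy particles before motion
#'   estimation. Set to 1 to disable.
#' @param box_work working box for the multi-particle driver: particles and
#'   reference are Fourier-cropped to this box before estimation (NULL =
#'   native box). Coefficients are dimensionless and the physical extent is
#'   preserved, so they apply to the full-size frame unchanged.
#' @param seed random seed recorded with results (estimation itself is
#'   deterministic).
#' @return an object of class `estimation_options`.
#' @export
estimation_options <- function(lambda1 = 0.005, max_sweeps = 5L, tol = 1e-4,
                               cancel_projection = TRUE,
                               line_interval = 0.15, line_tol = 2e-3,
                               lp_frac = 0.4, box_work = NULL, seed = 1L) {
  if (!is.finite(lambda1) || lambda1 < 0) stop("lambda1 must be >= 0")
  if (!is.finite(tol) || tol <= 0) stop("tol must be positive")
  structure(list(lambda1 = lambda1, max_sweeps = as.integer(max_sweeps),
                 tol = tol, cancel_projection = isTRUE(cancel_projection),
                 line_interval = line_interval, line_tol = line_tol,
                 lp_frac = lp_frac, box_work = box_work,
                 seed = as.integer(seed)),
            class = "estimation_options")
}

# Powell's conjugate-direction maximization. fn takes the flattened
# coefficient vector; project_fn (optional) maps an iterate back onto the
# feasible subspace after each sweep (projection-direction cancellation).
powell_maximize <- function(fn, x0, max_sweeps, tol, line_interval,
                            line_tol, project_fn = NULL) {
  ndim <- length(x0)
  dirs <- diag(ndim)
  x <- x0
  fx <- fn(x)
  f0 <- fx
  for (sweep in seq_len(max_sweeps)) {
    x_start <- x
    f_start <- fx
    best_gain <- 0
    best_dir <- 0L
    for (d in seq_len(ndim)) {
      u <- dirs[, d]
      ls <- optimize(function(t) fn(x + t * u),
                     interval = c(-line_interval, line_interval),
                     maximum = TRUE, tol = line_tol)
      if (ls$objective > fx) {
        gain <- ls$objective - fx
        if (gain > best_gain) { best_gain <- gain; best_dir <- d }
        x <- x + ls$maximum * u
        fx <- ls$objective
      }
    }
    # conjugate-direction update: try the net sweep displacement
    v <- x - x_start
    if (sqrt(sum(v^2)) > 1e-12) {
      u <- v / sqrt(sum(v^2))
      ls <- optimize(function(t) fn(x + t * u),
                     interval = c(-line_interval, line_interval),
                     maximum = TRUE, tol = line_tol)
      if (ls$objective > fx) {
        x <- x + ls$maximum * u
        fx <- ls$objective
      }
      if (best_dir > 0L) {
        dirs[, best_dir] <- u
      }
    }
    if (!is.null(project_fn)) {
      x <- project_fn(x)
      fx <- fn(x)
    }
    if (fx - f_start < tol) break
  }
  # the optimizer never returns below the start point
  if (fx < f0) { x <- x0; fx <- f0 }
  list(par = x, value = fx)
}

# Raised-cosine low-pass multiplier on the DFT grid of an n-box; cutoff at
# lp_frac * Nyquist with a 25 percent soft edge. lp_frac >= 1 disables it.
lowpass_multiplier <- function(n, lp_frac) {
  if (lp_frac >= 1) return(matrix(1, n, n))
  f <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / n
  fm <- sqrt(outer(f^2, f^2, "+"))
  fc <- 0.5 * lp_frac
  edge <- 0.25 * fc
  out <- matrix(0, n, n)
  out[fm <= fc] <- 1
  sel <- fm > fc & fm <= fc + edge
  out[sel] <- 0.5 * (1 + cos(pi * (fm[sel] - fc) / edge))
  out
}

# Shared forward model for one particle at a fixed pose: warp the reference
# with the coefficients, project, then apply CTF, shift and low-pass as one
# Fourier multiplier.
particle_forward_fn <- function(particle, v, spec, lp_frac = 1) {
  n <- vol_box(v)
  b <- ball_voxels(n)
  Z <- basis_matrix(spec, b$unit)
  Rt <- t(pose_matrix(particle$pose))
  mult <- shift_ramp(n, particle$pose$sx / v$voxel_size,
                     particle$pose$sy / v$voxel_size)
  if (!is.null(particle$ctf))
    mult <- mult * ctf_image(particle$ctf, n, particle$pixel_size)
  mult <- mult * lowpass_multiplier(n, lp_frac)
  scale_radius <- default_scale_radius(v)
  rvox <- scale_radius / v$voxel_size
  function(alpha) {
    vw <- cpp_warp_coeffs(v$values, b$ijk, Z, alpha, rvox)
    img <- cpp_project(vw, Rt, v$voxel_size)
    Re(fft(fft(img) * mult, inverse = TRUE)) / n^2
  }
}

#' Regularized estimation objective
#'
#' The quantity the Powell search maximizes: Pearson correlation between
#' the particle and the CTF-affected projection of the warped reference,
#' minus `lambda1` times the unit-ball integral of `||g||^2` with the
#' field expressed in voxel units of the estimation grid (the scale the
#' recommended `lambda1` range refers to; coefficients are
#' resolution-dependent quantities). Because the basis is orthonormal on
#' the unit ball, the integral equals `rvox^2` times the sum of squared
#' unit-ball coefficients exactly, so the penalty is evaluated in closed
#' form rather than by quadrature.
#'
#' @param c a [coefficient_set()].
#' @param particle a [particle_image()].
#' @param v the reference [volume_grid()].
#' @param lambda1 penalty weight.
#' @param lp_frac low-pass fraction applied to both sides of the
#'   correlation (1 = none); see [estimation_options()].
#' @return objective value (dimensionless).
#' @export
regularized_objective <- function(c, particle, v, lambda1, lp_frac = 1) {
  fwd <- particle_forward_fn(particle, v, c$spec, lp_frac)
  obs <- filter_image(particle$pixels, lp_frac)
  rvox <- c$scale_radius / v$voxel_size
  pearson_cor(obs, fwd(c$alphas)) - lambda1 * rvox^2 * sum(c$alphas^2)
}

filter_image <- function(img, lp_frac) {
  if (lp_frac >= 1) return(img)
  n <- nrow(img)
  Re(fft(fft(img) * lowpass_multiplier(n, lp_frac), inverse = TRUE)) / n^2
}

#' Estimate Zernike3D coefficients for one particle
#'
#' Maximizes the regularized correlation between the particle image and
#' the CTF-affected projection of the warped reference by Powell's
#' conjugate-direction method, starting from all-zero coefficients (no
#' deformation). With `cancel_projection` on, the field component along
#' the particle's viewing direction is removed after every sweep and from
#' the returned set, so the estimate only carries deformation the image
#' can actually constrain.
#'
#' @param particle a [particle_image()] with pose and CTF metadata.
#' @param v the reference [volume_grid()] (cubic, same box as the image).
#' @param spec a [basis_spec()].
#' @param opt an [estimation_options()].
#' @return list with `coeffs` (the estimated [coefficient_set()]) and
#'   `score` (final plain Pearson correlation).
#' @export
estimate_particle <- function(particle, v, spec, opt = estimation_options()) {
  stopifnot(inherits(particle, "particle_image"), inherits(v, "volume_grid"))
  if (nrow(particle$pixels) != vol_box(v))
    stop("particle box must match the reference box")
  if (sd(as.numeric(particle$pixels)) == 0)
    stop("blank particle: correlation undefined")
  fwd <- particle_forward_fn(particle, v, spec, opt$lp_frac)
  obs <- filter_image(particle$pixels, opt$lp_frac)
  k <- nrow(zernike_indices(spec))
  scale_radius <- default_scale_radius(v)
  rvox2 <- (scale_radius / v$voxel_size)^2
  fn <- function(x) {
    alpha <- matrix(x, ncol = 3)
    pearson_cor(obs, fwd(alpha)) - opt$lambda1 * rvox2 * sum(x^2)
  }
  project_fn <- NULL
  if (opt$cancel_projection) {
    d <- viewing_direction(particle$pose)
    project_fn <- function(x) {
      cs <- coeffs_unflatten(x, spec, scale_radius)
      coeffs_flatten(cancel_projection_component(cs, d))
    }
  }
  res <- powell_maximize(fn, rep(0, 3 * k), opt$max_sweeps, opt$tol,
                         opt$line_interval, opt$line_tol, project_fn)
  x <- if (is.null(project_fn)) res$par else project_fn(res$par)
  cs <- coeffs_unflatten(x, spec, scale_radius)
  list(coeffs = cs, score = pearson_cor(obs, fwd(cs$alphas)))
}

#' Estimate coefficients for a whole particle set
#'
#' Driver over [estimate_particle()]. When `opt$box_work` is smaller than
#' the native box, particles and reference are Fourier-cropped to the
#' working box first (band-limiting the data and shrinking the search
#' cost); the returned coefficients are dimensionless and the crop
#' preserves the physical box extent, so they apply to the full-size frame
#' directly.
#'
#' @param particles list of [particle_image()].
#' @param v the reference [volume_grid()].
#' @param spec a [basis_spec()].
#' @param opt an [estimation_options()].
#' @return list with `coeffs` (list of coefficient sets in particle order,
#'   with `scale_radius` of the native frame) and `scores` (numeric).
#' @export
estimate_particles <- function(particles, v, spec,
                               opt = estimation_options()) {
  box_full <- vol_box(v)
  v_work <- v
  work <- !is.null(opt$box_work) && opt$box_work < box_full
  if (work) v_work <- fourier_crop_volume(v, opt$box_work)
  out <- lapply(particles, function(p) {
    if (work) {
      p$pixels <- fourier_crop_image(p$pixels, opt$box_work)
      p$pixel_size <- p$pixel_size * box_full / opt$box_work
    }
    estimate_particle(p, v_work, spec, opt)
  })
  coeffs <- lapply(out, `[[`, "coeffs")
  if (work) {
    sr <- default_scale_radius(v)
    coeffs <- lapply(coeffs, function(cs) { cs$scale_radius <- sr; cs })
  }
  list(coeffs = coeffs, scores = vapply(out, `[[`, numeric(1), "score"))
}

#' Estimate coefficients between two volumes
#'
#' Volume-to-volume mode: the same regularized objective with the Pearson
#' correlation computed in 3D between the target map and the warped
#' reference — no CTF, no projection, no direction cancellation. Used to
#' place maps (e.g. discrete classes) into the same coefficient space as
#' particles.
#'
#' The default options differ from the particle mode: maps constrain the
#' field with far more (and far less noisy) observations than a single
#' projection, so the penalty is weaker (`lambda1 = 1e-4`) and the
#' convergence tolerance tighter (`tol = 1e-6`, 8 sweeps) — 3D
#' correlations sit very close to 1 and the informative objective gains
#' are small on that scale.
#'
#' @param target target [volume_grid()].
#' @param reference reference [volume_grid()] (same box and sampling).
#' @param spec a [basis_spec()].
#' @param opt an [estimation_options()].
#' @return list with `coeffs` and `score` (3D correlation).
#' @export
estimate_volume <- function(target, reference, spec,
                            opt = estimation_options(lambda1 = 1e-4,
                                                     max_sweeps = 8L,
                                                     tol = 1e-6)) {
  stopifnot(inherits(target, "volume_grid"),
            inherits(reference, "volume_grid"))
  if (vol_box(target) != vol_box(reference) ||
      abs(target$voxel_size - reference$voxel_size) > 1e-9)
    stop("target and reference must share box size and sampling")
  n <- vol_box(reference)
  b <- ball_voxels(n)
  Z <- basis_matrix(spec, b$unit)
  scale_radius <- default_scale_radius(reference)
  rvox <- scale_radius / reference$voxel_size
  obs <- as.numeric(target$values)
  k <- nrow(zernike_indices(spec))
  fn <- function(x) {
    vw <- cpp_warp_coeffs(reference$values, b$ijk, Z, matrix(x, ncol = 3),
                          rvox)
    cor(obs, as.numeric(vw)) - opt$lambda1 * rvox^2 * sum(x^2)
  }
  res <- powell_maximize(fn, rep(0, 3 * k), opt$max_sweeps, opt$tol,
                         opt$line_interval, opt$line_tol, NULL)
  cs <- coeffs_unflatten(res$par, spec, scale_radius)
  vw <- cpp_warp_coeffs(reference$values, b$ijk, Z, cs$alphas, rvox)
  list(coeffs = cs, score = cor(obs, as.numeric(vw)))
}
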