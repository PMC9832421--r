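#' Options for algebraic reconstruction
#'
#' @param lambda ART relaxation factor (default 1e-3).
#' @param epochs passes over the whole particle set (default 1).
#' @param seed shuffle seed: the per-epoch particle order is drawn from
#'   this seed, making runs reproducible.
#' @param positivity clamp the reconstruction to non-negative values after
#'   every update (default FALSE).
#' @param lambda_decay multiplicative relaxation decay per epoch
#'   (default 0.9).
#' @return an object of class `recon_options`.
#' @export
recon_options <- function(lambda = 1e-3, epochs = 1L, seed = 1L,
                          positivity = FALSE, lambda_decay = 0.9) {
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(lambda = lambda, epochs = as.integer(epochs),
                 seed = as.integer(seed), positivity = isTRUE(positivity),
                 lambda_decay = lambda_decay),
            class = "recon_options")
}

# Shared ART/ZART engine. coeffs NULL => plain ART. The ZART forward model
# for particle k is shift o CTF o P o W_{g_k}; the corrective update maps
# the backprojected residual back through the approximate inverse warp
# W_{-g_k} before adding it to the reconstruction (the adjoint of the
# deformed projector up to interpolation error). With all-zero coefficient
# sets every warp is the identity gather, so ZART reproduces ART bitwise.
art_engine <- function(particles, coeffs, box, opt) {
  if (length(particles) == 0) stop("empty particle list")
  if (!is.null(coeffs) && length(coeffs) != length(particles))
    stop("one coefficient set per particle is required")
  px <- particles[[1]]$pixel_size
  for (p in particles) {
    if (nrow(p$pixels) != box)
      stop("all particle boxes must equal the reconstruction box")
    if (abs(p$pixel_size - px) > 1e-9)
      stop("all particles must share one pixel size")
  }
  n <- box
  b <- ball_voxels(n)
  spec0 <- if (is.null(coeffs)) NULL else coeffs[[1]]$spec
  Z <- if (is.null(coeffs)) matrix(0, nrow(b$ijk), 1) else
    basis_matrix(spec0, b$unit)
  zero_alpha <- matrix(0, ncol(Z), 3)
  V <- array(0, dim = c(n, n, n))
  lam <- opt$lambda
  set.seed(opt$seed)
  for (epoch in seq_len(opt$epochs)) {
    ord <- sample(length(particles))
    for (i in ord) {
      p <- particles[[i]]
      alpha <- if (is.null(coeffs)) zero_alpha else coeffs[[i]]$alphas
      rvox <- if (is.null(coeffs)) 1 else coeffs[[i]]$scale_radius / px
      Rt <- t(pose_matrix(p$pose))
      mult <- shift_ramp(n, p$pose$sx / px, p$pose$sy / px)
      if (!is.null(p$ctf)) mult <- mult * ctf_image(p$ctf, n, px)
      Vw <- cpp_warp_coeffs(V, b$ijk, Z, alpha, rvox)
      theo <- Re(fft(fft(cpp_project(Vw, Rt, px)) * mult, inverse = TRUE)) / n^2
      resid <- p$pixels - theo
      # adjoint of (ramp * CTF): CTF is real and even (self-adjoint), the
      # shift adjoint is the conjugate ramp
      radj <- Re(fft(fft(resid) * Conj(mult), inverse = TRUE)) / n^2
      corr <- cpp_backproject(radj, n, Rt, px)
      corr <- cpp_warp_coeffs(corr, b$ijk, Z, -alpha, rvox)
      V <- V + lam * corr
      if (opt$positivity) V[V < 0] <- 0
    }
    lam <- lam * opt$lambda_decay
  }
  volume_grid(V, px)
}

#' ART reconstruction from a particle set
#'
#' Classic per-image algebraic reconstruction: starting from a zero volume,
#' each particle contributes the corrective update
#' `V <- V + lambda * P*(I - C P V)` (projector `P`, CTF `C`, adjoint
#' `P*`), iterating over the shuffled particle set for the requested
#' epochs. Deterministic for a fixed seed.
#'
#' @param particles list of [particle_image()] with consistent box and
#'   pixel size.
#' @param box reconstruction box in voxels (defaults to the particle box).
#' @param opt a [recon_options()].
#' @return the reconstructed [volume_grid()].
#' @export
art_reconstruct <- function(particles,
                            box = nrow(particles[[1]]$pixels),
                            opt = recon_options()) {
  art_engine(particles, NULL, box, opt)
}

#' ZART: deformation-aware ART reconstruction
#'
#' ART modified so each particle's correction is computed through that
#' particle's deformation field: the forward model warps the current
#' reconstruction with the particle's coefficients before projecting, and
#' the backprojected residual is mapped back through the approximate
#' inverse warp before being added. Undoing the per-particle conformational
#' change in this way reverts motion-induced blurring in flexible regions.
#' With all coefficient sets zero the result equals [art_reconstruct()]
#' exactly.
#'
#' @param particles list of [particle_image()].
#' @param coeffs list of [coefficient_set()], one per particle.
#' @param box reconstruction box in voxels.
#' @param opt a [recon_options()].
#' @return the reconstructed [volume_grid()].
#' @export
zart_reconstruct <- function(particles, coeffs,
                             box = nrow(particles[[1]]$pixels),
                             opt = recon_options()) {
  if (is.null(coeffs)) stop("coeffs is required; use art_reconstruct otherwise")
  art_engine(particles, coeffs, box, opt)
}
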