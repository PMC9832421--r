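#' Phantom specification
#'
#' A sum-of-Gaussian-blobs reference map plus a matching pseudo-atomic
#' model (one "atom" per blob centre), the stand-in for an experimental
#' reference used throughout testing. Blob centres must lie inside the
#' ball inscribed in the box.
#'
#' @param box box size in voxels (>= 16).
#' @param voxel_size Angstrom per voxel.
#' @param blobs data.frame with columns `x`, `y`, `z` (centres, Angstrom,
#'   centred frame), `sigma` (Angstrom) and `amplitude`. Default: an
#'   asymmetric three-domain scene, each domain a large Gaussian carrying
#'   four smaller satellite Gaussians (15 blobs total) — enough internal
#'   structure that a smooth deformation field is observable across the
#'   molecule, as it is for a real macromolecule.
#' @param seed recorded seed (generation itself is deterministic).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(box = 48L, voxel_size = 1.5,
                         blobs = NULL, seed = 1L) {
  box <- as.integer(box)
  if (box < 16L) stop("box must be at least 16 voxels")
  radius <- box / 2 * voxel_size
  if (is.null(blobs)) blobs <- default_phantom_blobs(radius)
  r <- sqrt(blobs$x^2 + blobs$y^2 + blobs$z^2)
  if (any(r > radius))
    stop("blob centre(s) outside the ball inscribed in the box")
  structure(list(box = box, voxel_size = voxel_size, blobs = blobs,
                 seed = as.integer(seed)), class = "phantom_spec")
}

# Deterministic three-domain layout: one core Gaussian per domain plus four
# satellites giving each domain internal structure.
default_phantom_blobs <- function(radius) {
  domains <- data.frame(
    x = c(0.30, -0.25, 0.05), y = c(0.05, 0.25, -0.35),
    z = c(-0.10, 0.25, 0.20),
    core_sigma = c(0.14, 0.12, 0.10), amp = c(1.0, 0.8, 0.9))
  sat <- matrix(c( 0.11,  0.05, -0.05,
                  -0.08,  0.10,  0.04,
                   0.02, -0.11,  0.08,
                  -0.05, -0.04, -0.11), ncol = 3, byrow = TRUE)
  out <- NULL
  for (i in seq_len(nrow(domains))) {
    d <- domains[i, ]
    out <- rbind(out,
                 data.frame(x = d$x, y = d$y, z = d$z, sigma = d$core_sigma,
                            amplitude = d$amp),
                 data.frame(x = d$x + sat[, 1] * (1 + 0.2 * i),
                            y = d$y + sat[, 2] * (1 + 0.15 * i),
                            z = d$z + sat[, 3] * (1 - 0.1 * i),
                            sigma = 0.055 + 0.01 * (seq_len(4) %% 2),
                            amplitude = 0.55 + 0.1 * (seq_len(4) %% 3)))
  }
  out[, c("x", "y", "z", "sigma")] <- out[, c("x", "y", "z", "sigma")] * radius
  out
}

#' Build a phantom volume and its pseudo-atomic model
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [volume_grid()]) and `model` (an
#'   [atomic_model()] with one atom per blob centre).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$box
  c0 <- floor(n / 2)
  ax <- ((0:(n - 1)) - c0) * spec$voxel_size
  gx <- array(rep(ax, times = n * n), dim = c(n, n, n))
  gy <- aperm(gx, c(2, 1, 3))
  gz <- aperm(gx, c(3, 2, 1))
  vals <- array(0, dim = c(n, n, n))
  for (i in seq_len(nrow(spec$blobs))) {
    bl <- spec$blobs[i, ]
    d2 <- (gx - bl$x)^2 + (gy - bl$y)^2 + (gz - bl$z)^2
    vals <- vals + bl$amplitude * exp(-d2 / (2 * bl$sigma^2))
  }
  mdl <- atomic_model(data.frame(
    element = rep("C", nrow(spec$blobs)), chain = "A",
    resid = seq_len(nrow(spec$blobs)),
    x = spec$blobs$x, y = spec$blobs$y, z = spec$blobs$z,
    stringsAsFactors = FALSE))
  list(volume = volume_grid(vals, spec$voxel_size), model = mdl)
}

#' Default bending-like deformation mode
#'
#' A smooth one-mode ground truth built from low-order terms: an `(l=1,
#' n=0)` transverse component plus an `(l=2, n=0)` component, scaled so
#' the mean displacement over the unit ball is `magnitude` (in unit-ball
#' units, i.e. fraction of the box radius).
#'
#' @param spec a [basis_spec()] (needs `N >= 2`, `L >= 2`).
#' @param scale_radius physical unit-ball radius in Angstrom.
#' @param magnitude mean displacement as a fraction of the box radius
#'   (default 0.03).
#' @return a [coefficient_set()].
#' @export
bending_mode <- function(spec, scale_radius, magnitude = 0.03) {
  idx <- zernike_indices(spec)
  alphas <- matrix(0, nrow(idx), 3)
  pick <- function(l, n, m) which(idx$l == l & idx$n == n & idx$m == m)
  # transverse x-displacement growing along z, plus a twist-like y term
  alphas[pick(1, 0, 0), 1] <- 1.0    # x-component ~ z
  alphas[pick(2, 0, 0), 2] <- 0.5
  alphas[pick(1, 0, 1), 2] <- 0.4    # y-component ~ x
  cs <- coefficient_set(spec, alphas, scale_radius)
  m0 <- deformation_magnitude(cs) / scale_radius
  scale_coefficients(cs, magnitude / m0)
}

#' In-plane deformation mode for a viewing direction
#'
#' Projects a mode onto the subspace observable from a given viewing
#' direction (no component along `d`); used to build ground truths whose
#' recovery a single image can be expected to achieve.
#'
#' @param mode a [coefficient_set()].
#' @param d viewing direction.
#' @return the in-plane part of the mode.
#' @export
inplane_mode <- function(mode, d) cancel_projection_component(mode, d)

#' Heterogeneity specification
#'
#' Ground-truth conformational variability for a synthetic dataset: a list
#' of deformation modes and a per-particle amplitude law. Laws:
#' `list(type = "uniform", min, max)` draws each mode amplitude uniformly;
#' `list(type = "mixture", centers, sd)` draws a cluster label uniformly
#' and the amplitude from a Gaussian around that cluster's centre
#' (two-state landscapes).
#'
#' @param modes list of [coefficient_set()] sharing one basis spec.
#' @param amplitude_law see above; default `uniform(-1, 1)`.
#' @param seed recorded seed.
#' @return an object of class `het_spec`.
#' @export
het_spec <- function(modes, amplitude_law = list(type = "uniform",
                                                 min = -1, max = 1),
                     seed = 1L) {
  stopifnot(length(modes) >= 1)
  for (m in modes) stopifnot(inherits(m, "coefficient_set"))
  structure(list(modes = modes, amplitude_law = amplitude_law,
                 seed = as.integer(seed)), class = "het_spec")
}

draw_amplitudes <- function(law, n_particles, n_modes) {
  if (law$type == "uniform") {
    matrix(runif(n_particles * n_modes, law$min, law$max),
           n_particles, n_modes)
  } else if (law$type == "mixture") {
    lab <- sample(seq_along(law$centers), n_particles, replace = TRUE)
    amp <- matrix(rnorm(n_particles * n_modes, mean = law$centers[lab],
                        sd = law$sd), n_particles, n_modes)
    attr(amp, "labels") <- lab
    amp
  } else stop("unknown amplitude law type")
}

#' Generate a synthetic particle dataset
#'
#' Realizes the forward model `I = C P_theta(V(r + g(r))) + noise` for
#' each particle with the package's own warp/project/CTF operators (the
#' estimation tests therefore probe inversion, not operator mismatch).
#' Per particle: mode amplitudes are drawn from the heterogeneity law, the
#' phantom is warped with the composed coefficient set, projected at a
#' random orientation (uniform on the sphere), CTF-modulated with a random
#' defocus, and white Gaussian noise is added at the requested SNR.
#'
#' SNR is defined as in-support signal variance over noise variance, the
#' support being the pixels where the clean image exceeds 1 percent of its
#' maximum magnitude.
#'
#' @param phantom list from [make_phantom()] (or any [volume_grid()] in
#'   `$volume`).
#' @param het a [het_spec()] or NULL for a homogeneous dataset.
#' @param n number of particles.
#' @param snr signal-to-noise ratio; `Inf` for noise-free.
#' @param seed random seed for poses, CTFs, amplitudes and noise.
#' @param defocus_range defocus draw range in Angstrom.
#' @param with_ctf set FALSE to skip CTF modulation entirely.
#' @return list with `particles` (list of [particle_image()], each
#'   carrying its ground-truth coefficient set), `truth` (list of
#'   coefficient sets), `labels` (cluster labels or NULL), `clean`
#'   (noise-free images) and `amplitudes`.
#' @export
make_dataset <- function(phantom, het, n, snr = Inf, seed = 1L,
                         defocus_range = c(8000, 20000), with_ctf = TRUE) {
  if (n < 1) stop("n must be >= 1")
  if (!(is.infinite(snr) || snr > 0)) stop("snr must be positive or Inf")
  v <- phantom$volume
  nb <- vol_box(v)
  scale_radius <- default_scale_radius(v)
  set.seed(seed)
  nm <- if (is.null(het)) 0L else length(het$modes)
  amp <- if (nm > 0) draw_amplitudes(het$amplitude_law, n, nm) else NULL
  labels <- if (!is.null(amp)) attr(amp, "labels") else NULL
  b <- ball_voxels(nb)
  spec0 <- if (nm > 0) het$modes[[1]]$spec else basis_spec(0, 0)
  Z <- basis_matrix(spec0, b$unit)
  rvox <- scale_radius / v$voxel_size
  particles <- vector("list", n)
  truth <- vector("list", n)
  clean <- vector("list", n)
  for (i in seq_len(n)) {
    alphas <- matrix(0, nrow(zernike_indices(spec0)), 3)
    if (nm > 0)
      for (j in seq_len(nm)) alphas <- alphas + amp[i, j] * het$modes[[j]]$alphas
    cs <- coefficient_set(spec0, alphas, scale_radius)
    pose <- particle_pose(rot = runif(1, 0, 360),
                          tilt = acos(runif(1, -1, 1)) * 180 / pi,
                          psi = runif(1, 0, 360))
    ctf <- if (with_ctf) {
      dfu <- runif(1, defocus_range[1], defocus_range[2])
      ctf_params(defocus_u = dfu, defocus_v = dfu * runif(1, 0.9, 1),
                 defocus_angle = runif(1, 0, 180))
    } else NULL
    vw <- cpp_warp_coeffs(v$values, b$ijk, Z, cs$alphas, rvox)
    img <- cpp_project(vw, t(pose_matrix(pose)), v$voxel_size)
    img <- apply_ctf(img, ctf, v$voxel_size)
    clean[[i]] <- img
    if (is.finite(snr)) {
      support <- abs(img) > 0.01 * max(abs(img))
      nsd <- sqrt(var(img[support]) / snr)
      img <- img + matrix(rnorm(nb * nb, sd = nsd), nb, nb)
    }
    truth[[i]] <- cs
    particles[[i]] <- particle_image(img, v$voxel_size, pose, ctf, id = i,
                                     truth_coeffs = cs)
  }
  list(particles = particles, truth = truth, labels = labels,
       clean = clean, amplitudes = amp)
}

#' Write a synthetic dataset to disk
#'
#' Emits the STAR metadata + MRC particle stack, the ground-truth
#' coefficient table, the clean (noise-free) stack for diagnostics, and
#' the phantom map.
#'
#' @param dataset list from [make_dataset()].
#' @param phantom list from [make_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_particles(dataset$particles, file.path(dir, "particles.star"))
  write_image_stack(dataset$clean, dataset$particles[[1]]$pixel_size,
                    file.path(dir, "clean.mrcs"))
  write_coeffs(dataset$truth, file.path(dir, "truth_coeffs.txt"))
  write_volume(phantom$volume, file.path(dir, "reference.mrc"))
  invisible(dir)
}
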