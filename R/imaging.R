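#' Particle pose
#'
#' Orientation as ZYZ intrinsic Euler angles in degrees (the RELION/Xmipp
#' convention, so STAR metadata round-trips without remapping) plus
#' in-plane shifts in Angstrom. The pose matrix is
#' `A = Rz(psi) %*% Ry(tilt) %*% Rz(rot)`; it maps reference-frame
#' coordinates to the projection frame, and the viewing axis in the
#' reference frame is `t(A) %*% c(0, 0, 1)`.
#'
#' @param rot,tilt,psi Euler angles in degrees; `tilt` in `[0, 180]`.
#' @param sx,sy in-plane shifts in Angstrom (applied to the projected
#'   image: content moves by `+s`).
#' @return an object of class `particle_pose`.
#' @export
particle_pose <- function(rot = 0, tilt = 0, psi = 0, sx = 0, sy = 0) {
  if (!is.finite(tilt) || tilt < 0 || tilt > 180)
    stop("tilt must lie in [0, 180] degrees")
  structure(list(rot = rot, tilt = tilt, psi = psi, sx = sx, sy = sy),
            class = "particle_pose")
}

rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

#' Pose rotation matrix (ZYZ intrinsic)
#'
#' @param pose a [particle_pose()].
#' @return 3x3 rotation matrix mapping reference to projection coordinates.
#' @export
pose_matrix <- function(pose) {
  d <- pi / 180
  rot_z(pose$psi * d) %*% rot_y(pose$tilt * d) %*% rot_z(pose$rot * d)
}

#' Viewing direction of a pose in the reference frame
#'
#' The unit vector along which the projection integrates; the direction
#' whose deformation component is unobservable and gets cancelled by
#' [cancel_projection_component()].
#'
#' @param pose a [particle_pose()].
#' @return unit 3-vector.
#' @export
viewing_direction <- function(pose) as.numeric(t(pose_matrix(pose)) %*% c(0, 0, 1))

#' CTF parameters
#'
#' @param defocus_u,defocus_v defocus along the astigmatism axes in
#'   Angstrom (underfocus positive).
#' @param defocus_angle astigmatism angle in degrees.
#' @param voltage acceleration voltage in kV.
#' @param cs spherical aberration in mm.
#' @param amplitude_contrast amplitude contrast fraction in `[0, 1]`.
#' @return an object of class `ctf_params`.
#' @export
ctf_params <- function(defocus_u = 15000, defocus_v = defocus_u,
                       defocus_angle = 0, voltage = 300, cs = 2.7,
                       amplitude_contrast = 0.1) {
  if (!is.finite(voltage) || voltage <= 0) stop("voltage must be positive")
  if (!all(is.finite(c(defocus_u, defocus_v)))) stop("defocus must be finite")
  if (amplitude_contrast < 0 || amplitude_contrast > 1)
    stop("amplitude_contrast must lie in [0, 1]")
  structure(list(defocus_u = defocus_u, defocus_v = defocus_v,
                 defocus_angle = defocus_angle, voltage = voltage, cs = cs,
                 amplitude_contrast = amplitude_contrast),
            class = "ctf_params")
}

# Relativistic electron wavelength in Angstrom, voltage in kV.
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1e3
  12.2639 / sqrt(v + 0.97845e-6 * v^2)
}

# DFT frequency axis in cycles/Angstrom.
fft_freqs <- function(n, pixel_size) {
  c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / (n * pixel_size)
}

#' Evaluate the CTF on the Fourier grid of a square image
#'
#' Phase-contrast transfer function
#' `CTF(f) = -sqrt(1 - A^2) sin(chi) - A cos(chi)` with the aberration
#' phase `chi(f) = pi lambda df(psi) |f|^2 - (pi/2) Cs lambda^3 |f|^4`,
#' astigmatic defocus
#' `df(psi) = (dU + dV)/2 + (dU - dV)/2 cos(2(psi - psi_ast))` and
#' underfocus positive.
#'
#' @param ctf a [ctf_params()].
#' @param n image box in pixels.
#' @param pixel_size Angstrom per pixel.
#' @return an `n` x `n` real matrix in DFT layout.
#' @export
ctf_image <- function(ctf, n, pixel_size) {
  f <- fft_freqs(n, pixel_size)
  fx <- matrix(f, n, n)
  fy <- t(fx)
  f2 <- fx^2 + fy^2
  psi <- atan2(fy, fx)
  lam <- electron_wavelength(ctf$voltage)
  df <- 0.5 * (ctf$defocus_u + ctf$defocus_v) +
    0.5 * (ctf$defocus_u - ctf$defocus_v) *
      cos(2 * (psi - ctf$defocus_angle * pi / 180))
  chi <- pi * lam * df * f2 - (pi / 2) * (ctf$cs * 1e7) * lam^3 * f2^2
  A <- ctf$amplitude_contrast
  H <- -sqrt(1 - A^2) * sin(chi) - A * cos(chi)
  # enforce exact evenness on the DFT grid (the astigmatic term is
  # asymmetric on the unpaired Nyquist lines of an even box), so the
  # filter maps real images to real images and is exactly self-adjoint
  idx <- c(1, n:2)
  (H + H[idx, idx]) / 2
}

#' Apply a CTF to an image
#'
#' Multiplies the discrete Fourier transform by the CTF and returns the
#' real part. The filter is real and even, hence self-adjoint — the
#' property the ART update relies on.
#'
#' @param img square numeric matrix.
#' @param ctf a [ctf_params()] (or NULL for a no-op).
#' @param pixel_size Angstrom per pixel.
#' @return filtered image.
#' @export
apply_ctf <- function(img, ctf, pixel_size) {
  if (is.null(ctf)) return(img)
  n <- nrow(img)
  stopifnot(ncol(img) == n)
  H <- ctf_image(ctf, n, pixel_size)
  Re(fft(fft(img) * H, inverse = TRUE)) / n^2
}

# Sub-pixel exact image translation by a Fourier phase ramp: content moves
# by (+dx, +dy) pixels.
fourier_shift_image <- function(img, dx, dy) {
  if (dx == 0 && dy == 0) return(img)
  n <- nrow(img)
  Re(fft(fft(img) * shift_ramp(n, dx, dy), inverse = TRUE)) / n^2
}

shift_ramp <- function(n, dx, dy) {
  f <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / n
  exp(-2i * pi * (outer(f * dx, f * dy, "+")))
}

#' Project a volume along a pose
#'
#' Real-space projection: the sampling grid is rotated by the pose, the
#' volume is integrated along the viewing axis (trilinear interpolation,
#' sum times voxel size) and the in-plane shift is applied as a Fourier
#' phase ramp (sub-pixel exact). Output box equals the volume box;
#' pixel size equals the voxel size.
#'
#' @param v a [volume_grid()].
#' @param pose a [particle_pose()].
#' @return square numeric matrix.
#' @export
project <- function(v, pose) {
  stopifnot(inherits(v, "volume_grid"))
  A <- pose_matrix(pose)
  img <- cpp_project(v$values, t(A), v$voxel_size)
  fourier_shift_image(img, pose$sx / v$voxel_size, pose$sy / v$voxel_size)
}

#' Backproject an image along a pose (exact adjoint of [project()])
#'
#' Satisfies the dot-product identity
#' `sum(project(v, pose) * img) == sum(v$values * backproject(img, pose)$values)`
#' for every volume and image: the interpolation weights are the exact
#' transpose of the projection's, and the shift adjoint is the opposite
#' phase ramp.
#'
#' @param img square numeric matrix.
#' @param pose a [particle_pose()].
#' @param box volume box in voxels (defaults to the image box).
#' @param voxel_size Angstrom per voxel.
#' @return a [volume_grid()].
#' @export
backproject <- function(img, pose, box = nrow(img), voxel_size = 1) {
  stopifnot(nrow(img) == ncol(img), nrow(img) == box)
  A <- pose_matrix(pose)
  img <- fourier_shift_image(img, -pose$sx / voxel_size,
                             -pose$sy / voxel_size)
  volume_grid(cpp_backproject(img, box, t(A), voxel_size), voxel_size)
}

#' Pearson correlation between two images
#'
#' The similarity measure maximized during coefficient estimation.
#'
#' @param a,b numeric arrays of identical shape.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_cor <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("images must share their shape")
  av <- as.numeric(a); bv <- as.numeric(b)
  if (sd(av) == 0 || sd(bv) == 0)
    stop("correlation undefined for a constant image")
  cor(av, bv)
}

#' Particle image with metadata
#'
#' The experimental datum: a square pixel array plus the pose and CTF under
#' which it was formed. `truth_coeffs` carries the generating coefficient
#' set for synthetic data only.
#'
#' @param pixels square numeric matrix.
#' @param pixel_size Angstrom per pixel.
#' @param pose a [particle_pose()].
#' @param ctf a [ctf_params()] or NULL (no CTF).
#' @param id identifier.
#' @param truth_coeffs optional generating [coefficient_set()].
#' @return an object of class `particle_image`.
#' @export
particle_image <- function(pixels, pixel_size, pose, ctf = NULL, id = NA,
                           truth_coeffs = NULL) {
  if (nrow(pixels) != ncol(pixels)) stop("particle image must be square")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be positive")
  stopifnot(inherits(pose, "particle_pose"))
  structure(list(pixels = pixels, pixel_size = pixel_size, pose = pose,
                 ctf = ctf, id = id, truth_coeffs = truth_coeffs),
            class = "particle_image")
}
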