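test_that("pose validation and the ZYZ convention are enforced", {
  expect_error(particle_pose(tilt = 190), "tilt")
  p <- particle_pose(rot = 30, tilt = 50, psi = 70)
  d <- pi / 180
  Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                             0, 0, 1), 3, 3)
  Ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                             sin(a), 0, cos(a)), 3, 3)
  expect_equal(pose_matrix(p),
               Rz(70 * d) %*% Ry(50 * d) %*% Rz(30 * d))
  expect_equal(sum(viewing_direction(p)^2), 1, tolerance = 1e-12)
  # top view looks along +z
  expect_equal(viewing_direction(particle_pose()), c(0, 0, 1))
})

test_that("projection conserves mass and matches the ray-sum oracle", {
  v <- tiny_phantom()$volume
  zero <- volume_grid(array(0, dim(v$values)), v$voxel_size)
  expect_equal(project(zero, particle_pose(10, 20, 30)),
               matrix(0, 32, 32))
  # identity pose: brute-force per-pixel ray sums are the oracle
  img <- project(v, particle_pose())
  oracle <- apply(v$values, c(1, 2), sum) * v$voxel_size
  expect_lt(rel_rmse(img, oracle), 1e-6)
  set.seed(21)
  mass_v <- sum(v$values) * v$voxel_size^3
  for (i in 1:5) {
    pose <- particle_pose(runif(1, 0, 360), acos(runif(1, -1, 1)) * 180 / pi,
                          runif(1, 0, 360))
    expect_equal(sum(project(v, pose)) * v$voxel_size^2, mass_v,
                 tolerance = 0.01)
  }
})

test_that("projection is linear and ignores rotations of a radial phantom", {
  v <- tiny_phantom()$volume
  set.seed(22)
  v2 <- volume_grid(array(rnorm(32^3), dim = c(32, 32, 32)), v$voxel_size)
  pose <- particle_pose(15, 75, 120)
  sum_v <- volume_grid(v$values + v2$values, v$voxel_size)
  expect_equal(project(sum_v, pose),
               project(v, pose) + project(v2, pose), tolerance = 1e-12)
  # centred spherically symmetric blob: projection is pose-invariant
  n <- 32; c0 <- 16
  ax <- (0:(n - 1)) - c0
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  ball <- volume_grid(array(exp(-r2 / 30), c(n, n, n)), 1.5)
  ref <- project(ball, particle_pose())
  for (i in 1:8) {
    pose <- particle_pose(runif(1, 0, 360), acos(runif(1, -1, 1)) * 180 / pi,
                          runif(1, 0, 360))
    expect_lt(rel_rmse(project(ball, pose), ref), 0.02)
  }
})

test_that("in-plane shifts move the projection content sub-pixel exactly", {
  v <- tiny_phantom()$volume
  pose0 <- particle_pose(40, 60, 10)
  poseS <- particle_pose(40, 60, 10, sx = 3 * v$voxel_size,
                         sy = -2 * v$voxel_size)
  base <- project(v, pose0)
  shifted <- project(v, poseS)
  # integer-pixel shift: compare by index displacement away from edges
  expect_equal(shifted[10:28, 10:28], base[7:25, 12:30], tolerance = 1e-6)
})

test_that("the CTF filter has the stated limiting forms and composes", {
  set.seed(23)
  img <- matrix(rnorm(48^2), 48)
  expect_equal(apply_ctf(matrix(0, 32, 32), ctf_params(), 1.5),
               matrix(0, 32, 32))
  # pure amplitude contrast, no aberration: unit-magnitude multiplier
  flat <- ctf_params(defocus_u = 0, cs = 0, amplitude_contrast = 1)
  out <- apply_ctf(img, flat, 1.5)
  expect_equal(sum(out^2), sum(img^2), tolerance = 1e-6)
  expect_equal(out, -img, tolerance = 1e-9)
  ctf <- ctf_params(15000, 13000, 30)
  twice <- apply_ctf(apply_ctf(img, ctf, 1.5), ctf, 1.5)
  H <- ctf_image(ctf, 48, 1.5)
  once_sq <- Re(fft(fft(img) * H^2, inverse = TRUE)) / 48^2
  expect_equal(twice, once_sq, tolerance = 1e-12)
  # homogeneity: scaling the image scales the filtered image
  expect_equal(apply_ctf(3 * img, ctf, 1.5), 3 * apply_ctf(img, ctf, 1.5),
               tolerance = 1e-12)
})

test_that("pearson correlation behaves at its extremes and under the null", {
  set.seed(24)
  x <- matrix(rnorm(128^2), 128)
  expect_equal(pearson_cor(x, x), 1)
  expect_equal(pearson_cor(x, -x), -1)
  expect_error(pearson_cor(x, matrix(1, 128, 128)), "constant")
  expect_error(pearson_cor(x, matrix(0, 64, 64)), "shape")
  # null distribution of the sample correlation: |rho| < 3/sqrt(npix)
  hits <- 0
  for (i in 1:20) {
    a <- matrix(rnorm(128^2), 128); b <- matrix(rnorm(128^2), 128)
    if (abs(pearson_cor(a, b)) < 3 / 128) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("backprojection is the exact adjoint of projection", {
  expect_equal(backproject(matrix(0, 24, 24), particle_pose(5, 15, 25),
                           24, 1.5)$values,
               array(0, c(24, 24, 24)))
  set.seed(25)
  for (i in 1:10) {
    pose <- particle_pose(runif(1, 0, 360), acos(runif(1, -1, 1)) * 180 / pi,
                          runif(1, 0, 360), runif(1, -4, 4), runif(1, -4, 4))
    v <- array(rnorm(24^3), c(24, 24, 24))
    img <- matrix(rnorm(24^2), 24)
    lhs <- sum(project(volume_grid(v, 1.5), pose) * img)
    rhs <- sum(v * backproject(img, pose, 24, 1.5)$values)
    expect_lt(abs(lhs - rhs) / max(abs(lhs), abs(rhs)), 1e-6)
  }
  # a single pixel backprojects to one constant ray along z
  one <- matrix(0, 24, 24); one[7, 9] <- 1
  bp <- backproject(one, particle_pose(), 24, 1)$values
  expect_equal(bp[7, 9, ], rep(1, 24))
  bp[7, 9, ] <- 0
  expect_equal(max(abs(bp)), 0)
})
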