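spec <- basis_spec(3, 2)

make_noiseless_particle <- function(v, pose, ctf = ctf_params(12000),
                                    coeffs = NULL) {
  vv <- if (is.null(coeffs)) v else warp_volume(v, coeffs)
  img <- apply_ctf(project(vv, pose), ctf, v$voxel_size)
  particle_image(img, v$voxel_size, pose, ctf)
}

test_that("the regularized objective decomposes as correlation minus penalty", {
  v <- tiny_phantom()$volume
  sr <- default_scale_radius(v)
  pose <- particle_pose(20, 70, 110)
  p <- make_noiseless_particle(v, pose)
  zero <- coefficient_set(spec, NULL, sr)
  expect_equal(regularized_objective(zero, p, v, lambda1 = 0.5),
               pearson_cor(p$pixels,
                           apply_ctf(project(v, pose), p$ctf, v$voxel_size)),
               tolerance = 1e-12)
  set.seed(31)
  cs <- random_coeffs(spec, sr, sd = 0.01)
  rho <- function(c, lam) regularized_objective(c, p, v, lam)
  pen1 <- rho(cs, 0) - rho(cs, 0.001)
  pen2 <- rho(scale_coefficients(cs, 2), 0) -
    rho(scale_coefficients(cs, 2), 0.001)
  expect_equal(pen2, 4 * pen1, tolerance = 1e-8)
  # strictly decreasing in lambda1 while the field is nonzero
  expect_gt(rho(cs, 0.001), rho(cs, 0.005))
  expect_gt(rho(cs, 0.005), rho(cs, 0.02))
})

test_that("the conjugate-direction optimizer solves a quadratic exactly", {
  tgt <- c(0.05, -0.03, 0.08)
  fn <- function(x) -sum((x - tgt)^2)
  res <- zflex:::powell_maximize(fn, c(0, 0, 0), max_sweeps = 5, tol = 1e-10,
                                 line_interval = 0.15, line_tol = 1e-5)
  expect_equal(res$par, tgt, tolerance = 1e-3)
  # never returns an objective below the start
  bad <- zflex:::powell_maximize(function(x) -sum(x^2), c(0, 0, 0),
                                 max_sweeps = 2, tol = 1e-8,
                                 line_interval = 0.1, line_tol = 1e-3)
  expect_gte(bad$value, -1e-12)
})

test_that("a noiseless undeformed particle estimates as no deformation", {
  v <- tiny_phantom()$volume
  sr <- default_scale_radius(v)
  p <- make_noiseless_particle(v, particle_pose(35, 55, 200))
  est <- estimate_particle(p, v, spec, estimation_options(max_sweeps = 3))
  expect_lt(deformation_magnitude(est$coeffs) / sr, 0.02)
  expect_gt(est$score, 0.99)
})

test_that("a dominant penalty drives the estimate to zero deformation", {
  v <- tiny_phantom()$volume
  sr <- default_scale_radius(v)
  set.seed(32)
  cs <- random_coeffs(spec, sr, sd = 0.01)
  p <- make_noiseless_particle(v, particle_pose(80, 40, 10), coeffs = cs)
  est <- estimate_particle(p, v, spec,
                           estimation_options(lambda1 = 10, max_sweeps = 2))
  expect_lt(deformation_magnitude(est$coeffs) / sr, 1e-3)
})

test_that("estimation is invariant to positive image scaling", {
  v <- tiny_phantom()$volume
  set.seed(33)
  cs <- random_coeffs(spec, default_scale_radius(v), sd = 0.01)
  p <- make_noiseless_particle(v, particle_pose(10, 100, 300), coeffs = cs)
  p2 <- p; p2$pixels <- 7.3 * p$pixels
  opt <- estimation_options(max_sweeps = 2)
  e1 <- estimate_particle(p, v, spec, opt)
  e2 <- estimate_particle(p2, v, spec, opt)
  expect_equal(e1$coeffs$alphas, e2$coeffs$alphas, tolerance = 1e-10)
  expect_equal(e1$score, e2$score, tolerance = 1e-10)
})

test_that("estimates honour the projection-direction constraint", {
  v <- tiny_phantom()$volume
  set.seed(34)
  cs <- random_coeffs(spec, default_scale_radius(v), sd = 0.012)
  pose <- particle_pose(130, 65, 20)
  p <- make_noiseless_particle(v, pose, coeffs = cs)
  est <- estimate_particle(p, v, spec, estimation_options(max_sweeps = 2))
  d <- viewing_direction(pose)
  g <- evaluate_field(est$coeffs, ball_points(100))
  expect_lt(max(abs(g %*% d)), 1e-8 * max(1e-12, max(abs(g))))
})

test_that("blank particles and shape mismatches are rejected", {
  v <- tiny_phantom()$volume
  blank <- particle_image(matrix(0, 32, 32), v$voxel_size, particle_pose())
  expect_error(estimate_particle(blank, v, spec), "blank")
  small <- particle_image(matrix(rnorm(24^2), 24), v$voxel_size,
                          particle_pose())
  expect_error(estimate_particle(small, v, spec), "box")
})

test_that("volume-to-volume estimation recovers identity and small warps", {
  ph <- make_phantom(phantom_spec())
  v <- ph$volume
  sr <- default_scale_radius(v)
  e0 <- estimate_volume(v, v, spec)
  expect_gt(e0$score, 0.999)
  expect_lt(deformation_magnitude(e0$coeffs) / sr, 0.01)
  # known small warp: field recovered within 20 percent over the mask
  mode <- bending_mode(spec, sr, magnitude = 0.03)
  tgt <- warp_volume(v, mode)
  e1 <- estimate_volume(tgt, v, spec)
  msk <- molecular_mask(v)
  sel <- which(msk$values > 0)
  pts <- (arrayInd(sel, dim(msk$values)) - 1 - 24) / 24
  gt <- evaluate_field(mode, pts)
  ge <- evaluate_field(e1$coeffs, pts)
  expect_lt(sqrt(mean(rowSums((ge - gt)^2))) /
              sqrt(mean(rowSums(gt^2))), 0.2)
  expect_error(estimate_volume(fourier_crop_volume(v, 32), v, spec),
               "share")
})

test_that("fitting a rotated map cannot do worse than the zero start", {
  ph <- make_phantom(phantom_spec())
  v <- ph$volume
  d <- pi / 180
  A <- matrix(c(cos(5 * d), sin(5 * d), 0, -sin(5 * d), cos(5 * d), 0,
                0, 0, 1), 3, 3)
  n <- vol_box(v); c0 <- floor(n / 2)
  grid <- as.matrix(expand.grid(x = 0:(n - 1), y = 0:(n - 1),
                                z = 0:(n - 1))) - c0
  pts <- grid %*% A + c0
  rot <- volume_grid(array(zflex:::cpp_trilinear(v$values, pts), dim(v$values)),
                     v$voxel_size)
  base_cor <- cor(as.numeric(rot$values), as.numeric(v$values))
  est <- estimate_volume(rot, v, spec,
                         estimation_options(lambda1 = 1e-4, max_sweeps = 4,
                                            tol = 1e-6))
  expect_gt(est$score, base_cor)
})

test_that("particle and volume modes agree in the degenerate limit", {
  ph <- make_phantom(phantom_spec())
  v <- ph$volume
  sr <- default_scale_radius(v)
  mode <- bending_mode(spec, sr, magnitude = 0.035)
  mode_ip <- cancel_projection_component(mode, c(0, 0, 1))
  tgt <- warp_volume(v, mode_ip)
  # a "particle" with identity pose and no CTF is just the target's z-sum
  p <- particle_image(project(tgt, particle_pose()), v$voxel_size,
                      particle_pose(), ctf = NULL)
  # noiseless data: no low-pass, weak penalty, tight convergence
  ep <- estimate_particle(p, v, spec,
                         estimation_options(lambda1 = 1e-4, max_sweeps = 5,
                                            tol = 1e-6, lp_frac = 1))
  ev <- estimate_volume(tgt, v, spec)
  ip <- function(cs) {
    a <- cancel_projection_component(cs, c(0, 0, 1))$alphas
    as.vector(a[, 1:2])
  }
  expect_gt(cor(ip(ep$coeffs), ip(ev$coeffs)), 0.8)
})
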