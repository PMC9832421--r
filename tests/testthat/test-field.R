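spec <- basis_spec(3, 2)

test_that("field evaluation is linear and matches the constant mode", {
  sr <- 100
  zero <- coefficient_set(spec, NULL, sr)
  pts <- rbind(c(0, 0, 0), c(0.3, -0.2, 0.5), c(0.9, 0, 0))
  expect_equal(evaluate_field(zero, pts), matrix(0, 3, 3),
               ignore_attr = TRUE)
  a <- matrix(0, 13, 3); a[1, 1] <- 1
  cs <- coefficient_set(spec, a, sr)
  g <- evaluate_field(cs, pts)
  expect_equal(g[, 1], rep(sqrt(3) / (2 * sqrt(pi)), 3), tolerance = 1e-12)
  expect_equal(g[, 2:3], matrix(0, 3, 2), ignore_attr = TRUE)
  set.seed(2)
  c1 <- random_coeffs(spec, sr); c2 <- random_coeffs(spec, sr)
  expect_equal(evaluate_field(add_coefficients(c1, c2), pts),
               evaluate_field(c1, pts) + evaluate_field(c2, pts))
})

test_that("warping with zero coefficients returns the volume untouched", {
  v <- tiny_phantom()$volume
  cs <- coefficient_set(spec, NULL, default_scale_radius(v))
  expect_identical(warp_volume(v, cs)$values, v$values)
})

test_that("a constant field warps like a rigid shift of the density", {
  # band-limited phantom: blob widths of at least two voxels keep the
  # trilinear interpolation error within the stated tolerance
  blobs <- data.frame(x = c(8, -6, 0), y = c(2, 6, -9), z = c(-3, 7, 5),
                      sigma = c(5, 4, 3.5), amplitude = c(1, 0.8, 0.9))
  sp <- phantom_spec(box = 32, voxel_size = 1.5, blobs = blobs)
  v <- make_phantom(sp)$volume
  sr <- default_scale_radius(v)
  shift_unit <- 0.04
  a <- matrix(0, 13, 3)
  a[1, 1] <- shift_unit / (sqrt(3) / (2 * sqrt(pi)))
  cs <- coefficient_set(spec, a, sr)
  w <- warp_volume(v, cs)
  # independent oracle: the phantom is analytic, so evaluate the Gaussians
  # at coordinates shifted by +g (gather convention)
  n <- 32; c0 <- 16
  ax <- ((0:(n - 1)) - c0) * 1.5
  grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  shifted <- cbind(grid[, 1] + shift_unit * sr, grid[, 2], grid[, 3])
  va <- numeric(nrow(grid))
  for (i in seq_len(nrow(blobs))) {
    b <- blobs[i, ]
    va <- va + b$amplitude *
      exp(-((shifted[, 1] - b$x)^2 + (shifted[, 2] - b$y)^2 +
              (shifted[, 3] - b$z)^2) / (2 * b$sigma^2))
  }
  oracle <- array(va, c(n, n, n))
  inside <- array(sqrt(rowSums((grid / sr)^2)) <= 0.9, c(n, n, n))
  dev <- max(abs(w$values[inside] - oracle[inside]))
  expect_lt(dev / diff(range(v$values)), 0.05)
})

test_that("warping with c then -c recovers the volume to first order", {
  v <- tiny_phantom()$volume
  sr <- default_scale_radius(v)
  set.seed(3)
  cs <- random_coeffs(spec, sr, sd = 0.01)
  back <- warp_volume(warp_volume(v, cs), negate_coefficients(cs))
  stray <- warp_volume(v, scale_coefficients(cs, 2))
  expect_lt(sqrt(mean((back$values - v$values)^2)),
            sqrt(mean((stray$values - v$values)^2)))
})

test_that("model warping displaces atoms by the field and flags outliers", {
  sr <- 100
  mdl <- atomic_model(data.frame(element = "C", chain = "A", resid = 1,
                                 x = 0, y = 0, z = 0))
  zero <- coefficient_set(spec, NULL, sr)
  expect_equal(warp_model(mdl, zero)$atoms, mdl$atoms)
  a <- matrix(0, 13, 3); a[1, 2] <- 0.1 / (sqrt(3) / (2 * sqrt(pi)))
  cs <- coefficient_set(spec, a, sr)
  moved <- warp_model(mdl, cs)
  expect_equal(c(moved$atoms$x, moved$atoms$y, moved$atoms$z),
               c(0, 10, 0), tolerance = 1e-10)
  far <- atomic_model(data.frame(element = "C", chain = "A", resid = 1:2,
                                 x = c(0, 150), y = 0, z = 0))
  expect_warning(wf <- warp_model(far, cs), "outside")
  expect_equal(wf$atoms$x[2], 150)
})

test_that("model and map deform consistently under the sign convention", {
  ph <- tiny_phantom()
  v <- ph$volume
  sr <- default_scale_radius(v)
  set.seed(4)
  cs <- random_coeffs(spec, sr, sd = 0.015)
  vw <- warp_volume(v, cs)
  mw <- warp_model(ph$model, negate_coefficients(cs))
  rw <- render_model(mw, vol_box(v), v$voxel_size, sigma = 4)
  r0 <- render_model(ph$model, vol_box(v), v$voxel_size, sigma = 4)
  # rendering of the co-deformed model should track the warped map better
  # than the undeformed rendering does
  expect_gt(cor(as.numeric(rw$values), as.numeric(vw$values)),
            cor(as.numeric(r0$values), as.numeric(vw$values)))
})

test_that("coefficient rotation realizes the closure property", {
  sr <- 80
  set.seed(5)
  cs <- random_coeffs(spec, sr)
  expect_equal(rotate_coefficients(cs, diag(3))$alphas, cs$alphas,
               tolerance = 1e-12)
  # l=0 block mixes only the vector parts: x -> y under a 90 deg z-rotation
  a <- matrix(0, 13, 3); a[1, 1] <- 1
  cx <- coefficient_set(spec, a, sr)
  Rz90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  cy <- rotate_coefficients(cx, Rz90)
  expect_equal(cy$alphas[1, ], c(x = 0, y = 1, z = 0), tolerance = 1e-12)
  expect_lt(max(abs(cy$alphas[-1, ])), 1e-12)
  for (rep in 1:10) {
    A <- random_rotation()
    cr <- rotate_coefficients(cs, A)
    pts <- ball_points(40)
    lhs <- evaluate_field(cr, pts)
    rhs <- evaluate_field(cs, pts %*% A) %*% t(A)
    expect_lt(max(abs(lhs - rhs)), 1e-10)
    back <- rotate_coefficients(cr, t(A))
    expect_lt(max(abs(back$alphas - cs$alphas)), 1e-10)
  }
  expect_error(rotate_coefficients(cs, diag(3) * 2), "rotation")
})

test_that("grid-level rotation closure is weaker than the continuous one", {
  # the basis closes under rotations in continuous space only; through the
  # voxel grid the same comparison picks up interpolation error
  ph <- tiny_phantom()
  v <- ph$volume
  sr <- default_scale_radius(v)
  set.seed(6)
  cs <- random_coeffs(spec, sr, sd = 0.015)
  A <- rot_z90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  cr <- rotate_coefficients(cs, A)
  # rotate the volume by 90 deg about z exactly (grid-aligned), then warp
  vrot <- v; vrot$values <- aperm(v$values[, dim(v$values)[2]:1, ], c(2, 1, 3))
  w1 <- warp_volume(vrot, cr)$values
  w2 <- warp_volume(v, cs)$values
  w2rot <- aperm(w2[, dim(w2)[2]:1, ], c(2, 1, 3))
  grid_err <- max(abs(w1 - w2rot))
  pts <- ball_points(100)
  cont_err <- max(abs(evaluate_field(cr, pts) -
                        evaluate_field(cs, pts %*% A) %*% t(A)))
  expect_gt(grid_err, cont_err)
})

test_that("projection-direction cancellation removes exactly the axial part", {
  sr <- 80
  set.seed(7)
  cs <- random_coeffs(spec, sr)
  # d = +Z equals zeroing the z column directly
  cz <- cancel_projection_component(cs, c(0, 0, 1))
  direct <- cs; direct$alphas[, 3] <- 0
  expect_equal(cz$alphas, direct$alphas, tolerance = 1e-10)
  zero <- coefficient_set(spec, NULL, sr)
  expect_equal(cancel_projection_component(zero, c(1, 1, 0))$alphas,
               zero$alphas)
  expect_error(cancel_projection_component(cs, c(0, 0, 0)), "nonzero")
})

test_that("rescaling is exact and commutes with evaluation", {
  sr <- 64
  set.seed(8)
  cs <- random_coeffs(spec, sr)
  expect_identical(rescale_coefficients(cs, 1), cs)
  up <- rescale_coefficients(cs, 2)
  expect_identical(up$alphas, cs$alphas * 2)
  expect_identical(up$scale_radius, sr * 2)
  round_trip <- rescale_coefficients(up, 0.5)
  expect_identical(round_trip$alphas, cs$alphas)
  expect_identical(round_trip$scale_radius, cs$scale_radius)
  pts <- ball_points(20)
  k <- 1.7
  expect_equal(evaluate_field(rescale_coefficients(cs, k), pts),
               k * evaluate_field(cs, pts), tolerance = 1e-12)
  expect_error(rescale_coefficients(cs, 0), "positive")
})

test_that("deformation magnitude has the closed-form constant-field value", {
  sr <- 100
  zero <- coefficient_set(spec, NULL, sr)
  expect_equal(deformation_magnitude(zero), 0)
  a <- matrix(0, 13, 3); a[1, 1] <- 0.05 / (sqrt(3) / (2 * sqrt(pi)))
  cs <- coefficient_set(spec, a, sr)
  expect_equal(deformation_magnitude(cs), 5, tolerance = 1e-9)
  set.seed(9)
  cr <- random_coeffs(spec, sr)
  expect_equal(deformation_magnitude(scale_coefficients(cr, 2)),
               2 * deformation_magnitude(cr), tolerance = 1e-12)
  empty <- volume_grid(array(0, c(16, 16, 16)), 1)
  expect_error(deformation_magnitude(cr, empty), "mask")
})

test_that("coefficient tables round-trip bit-exactly and reject bad files", {
  sr <- 48
  set.seed(10)
  sets <- list(random_coeffs(spec, sr), random_coeffs(spec, sr))
  path <- withr::local_tempfile(fileext = ".txt")
  write_coeffs(sets, path)
  back <- read_coeffs(path)
  expect_length(back, 2)
  expect_identical(back[[1]]$alphas, sets[[1]]$alphas)
  expect_identical(back[[2]]$alphas, sets[[2]]$alphas)
  expect_identical(back[[1]]$scale_radius, sr)
  lines <- readLines(path)
  writeLines(lines[-5], path)
  expect_error(read_coeffs(path), "multiple")
})
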