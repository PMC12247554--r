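# Rigid transform and Gauss-Newton registration.

test_that("zero-parameter transform is the identity, bit-exact", {
  v <- gaussian_volume()
  expect_identical(transform_volume(v, rep(0, 6)), v)
})

test_that("integer-voxel translation equals an index shift on the interior", {
  v <- gaussian_volume()
  out <- transform_volume(v, c(0, 0, 0, 3, 0, 0))  # +1 voxel along x
  expect_identical(out[4:19, , ], v[3:18, , ])
})

test_that("transform round trip recovers the input on a smooth volume", {
  v <- gaussian_volume(sigma_mm = 8)
  p <- c(1.2, -0.8, 2.0, 1.5, -2.2, 0.9)
  back <- transform_volume(transform_volume(v, p), p, invert = TRUE)
  expect_lt(max(abs((back - v)[3:18, 3:18, 3:14])), 0.01 * diff(range(v)))
})

test_that("non-finite transform parameters are rejected", {
  v <- gaussian_volume()
  expect_error(transform_volume(v, c(0, 0, 0, NA, 0, 0)), "finite")
})

test_that("spatial derivative of a constant image vanishes on the interior", {
  v <- array(7, small_dims)
  d <- spatial_derivative(v, "Ty")$values
  expect_equal(max(abs(d[3:18, 3:18, 3:14])), 0)
})

test_that("translation derivative of a linear ramp is minus the gradient", {
  # movement-of-volume convention: content moving +x lowers the value seen
  # at a fixed voxel by the spatial gradient, so d = -dI/dx = -1 here
  dims <- small_dims
  x_mm <- array((seq_len(dims[1]) - 1 - (dims[1] - 1) / 2) * 3, dims)
  d <- spatial_derivative(x_mm, "Tx")$values
  expect_equal(max(abs(d[4:17, 4:17, 4:13] + 1)), 0, tolerance = 1e-3)
})

test_that("Tz derivative of the phantom is positive superior, negative inferior", {
  ph <- small_phantom()
  d <- spatial_derivative(ph$s0_map, "Tz")$values
  top <- d[9:11, 9:11, 13]
  bottom <- d[9:11, 9:11, 4]
  expect_true(all(top > 0))
  expect_true(all(bottom < 0))
})

test_that("registering a volume to itself gives zero parameters and SSE", {
  v <- gaussian_volume()
  fit <- register_volume(v, v)
  expect_equal(unname(fit$params), rep(0, 6))
  expect_equal(fit$sse, 0)
  expect_true(fit$converged)
})

test_that("single-axis motion is recovered within 0.05 mm / deg", {
  ph <- small_phantom()
  ref <- ph$s0_map
  moved_t <- transform_volume(ref, c(0, 0, 0, 0, 0, 1.5))
  fit_t <- register_volume(moved_t, ref)
  expect_equal(unname(fit_t$params[6]), 1.5, tolerance = 0.05)
  expect_lt(max(abs(fit_t$params[-6])), 0.05)
  moved_r <- transform_volume(ref, c(0, 0, 2, 0, 0, 0))
  fit_r <- register_volume(moved_r, ref)
  expect_equal(unname(fit_r$params[3]), 2, tolerance = 0.05)
  expect_lt(max(abs(fit_r$params[4:6])), 0.05)
})

test_that("refreshing the Jacobian gives the same recovery", {
  ph <- small_phantom()
  ref <- ph$s0_map
  moved <- transform_volume(ref, c(0, 1.0, 0, 0, 2.0, 0))
  a <- register_volume(moved, ref)
  b <- register_volume(moved, ref, refresh_jacobian = TRUE)
  expect_equal(a$params, b$params, tolerance = 0.02)
})

test_that("estimate matches a dense SSE-scan oracle for pure translation", {
  ph <- small_phantom()
  ref <- ph$s0_map
  true_ty <- 1.23
  moved <- transform_volume(ref, c(0, 0, 0, 0, true_ty, 0))
  grid <- seq(0, 2.5, by = 0.01)
  sse <- vapply(grid, function(g)
    sum((transform_volume(ref, c(0, 0, 0, 0, g, 0)) - moved)^2), numeric(1))
  oracle <- grid[which.min(sse)]
  fit <- register_volume(moved, ref)
  expect_equal(unname(fit$params[5]), oracle, tolerance = 0.05)
})

test_that("zero-variance reference is rejected", {
  v <- array(0, small_dims)
  expect_error(register_volume(gaussian_volume(), v), "zero variance")
})

test_that("register_run recovers known motion and is deterministic", {
  ph <- small_phantom()
  K <- 10
  truth <- simulate_motion(K, "mixed", 1.5, seed = 21)
  run <- small_run(K = K, asym = c(0, 0), base_c = 0, motion = truth,
                   noise_sd = 5, seed = 3)
  est <- register_run(run$echoes[[1]], 1L)
  err <- unclass(est) - unclass(truth)
  expect_lt(max(sqrt(colMeans(err^2))), 0.05)
  expect_true(all(unclass(est)[1, ] == 0))
  est2 <- register_run(run$echoes[[1]], 1L)
  expect_identical(unclass(est), unclass(est2))
})

test_that("a run of identical volumes registers to the zero matrix", {
  run <- small_run(K = 4, asym = c(0, 0), base_c = 0)
  est <- register_run(run$echoes[[2]], 1L)
  expect_equal(max(abs(unclass(est))), 0, tolerance = 1e-3)
})

test_that("echo equivalence without BOLD: me2 - me1 stays below 0.02", {
  # with zero coupling the two echoes differ only by TE decay scaling and
  # noise; at low noise the motion estimates must agree per axis, which is
  # what licenses reading me2 - me1 as a pure bias signal
  run <- simulate_run(55, 1, asym_coeffs = c(0, 0), coupling_scale = 0,
                      motion_profile = "drift", motion_amplitude = 1.0,
                      noise_sd = 1, n_volumes = 12)
  me1 <- register_run(run$echoes[[1]], 1L)
  me2 <- register_run(run$echoes[[2]], 1L)
  expect_lt(max(abs(unclass(me2) - unclass(me1))), 0.02)
})
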