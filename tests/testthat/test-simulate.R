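# Synthetic-data generator: phantom geometry, driver, motion, rendering.

test_that("phantom coupling map follows the asymmetry formula and mask", {
  ph <- small_phantom(asym = c(0.5, 0.5), base_c = 0.02)
  # zero outside the brain
  expect_true(all(ph$coupling_map[!ph$brain_mask] == 0))
  expect_true(all(ph$s0_map >= 0))
  expect_true(all(ph$s0_map[!ph$brain_mask] == 0))
  # independent formula evaluation at fully-interior voxels (no edge taper):
  # recompute the normalized ellipsoid radius from coordinates
  dims <- dim(ph$coupling_map)
  ctr <- (dims - 1) / 2
  grid <- as.matrix(expand.grid(i = 1:dims[1], j = 1:dims[2], k = 1:dims[3]))
  xh <- (grid[, 1] - 1 - ctr[1]) * 3 / 27
  yh <- (grid[, 2] - 1 - ctr[2]) * 3 / 21
  zh <- (grid[, 3] - 1 - ctr[3]) * 3 / 15
  rho <- sqrt(xh^2 + yh^2 + zh^2)
  interior <- grid[rho < 0.8, , drop = FALSE]  # inside the edge taper shell
  yhat <- yh[rho < 0.8]
  zhat <- zh[rho < 0.8]
  expect_gt(nrow(interior), 50)
  expected <- 0.02 * pmax(0, 1 + 0.5 * yhat + 0.5 * zhat)
  expect_equal(ph$coupling_map[interior], expected, tolerance = 1e-12)
  # superior-posterior interior coupling exceeds the centre value
  cen <- ph$coupling_map[ctr[1] + 1, ctr[2] + 1, ctr[3] + 1]
  expect_gt(max(ph$coupling_map[interior]), 1.3 * cen)
})

test_that("symmetric phantom is mirror-symmetric across mid-planes", {
  ph <- small_phantom(asym = c(0, 0))
  c_map <- ph$coupling_map
  expect_equal(c_map, c_map[, rev(seq_len(dim(c_map)[2])), ])
  expect_equal(c_map, c_map[, , rev(seq_len(dim(c_map)[3]))])
})

test_that("oversized ellipsoid is rejected", {
  expect_error(make_phantom(c(16, 16, 16), c(3, 3, 3), c(40, 40, 40)),
               "exceeds the grid")
})

test_that("gs driver is reproducible, standardized and smooth", {
  a <- simulate_gs_driver(200, 3, 0.1, seed = 5)
  b <- simulate_gs_driver(200, 3, 0.1, seed = 5)
  expect_identical(a, b)
  expect_lt(abs(mean(a)), 1e-12)
  expect_equal(sd(a), 1, tolerance = 1e-12)
  # slow driver has strong lag-1 autocorrelation (median over seeds)
  lag1 <- vapply(1:100, function(s) {
    x <- simulate_gs_driver(200, 3, 0.05, seed = s)
    cor(x[-1], x[-200])
  }, numeric(1))
  expect_gt(median(lag1), 0.5)
  expect_error(simulate_gs_driver(100, 3, 0.2), "Nyquist")
})

test_that("motion profiles respect the reference frame and spike counts", {
  z <- simulate_motion(30, "none", 1, seed = 1)
  expect_true(all(unclass(z) == 0))
  for (p in c("drift", "spikes", "mixed")) {
    m <- simulate_motion(50, p, 1.0, seed = 3)
    expect_true(all(unclass(m)[1, ] == 0))
    # drift and spikes are each bounded by the amplitude; "mixed" adds them
    bound <- if (p == "mixed") 2.0 else 1.0
    expect_lte(max(abs(unclass(m))), bound + 1e-12)
  }
  sp <- unclass(simulate_motion(50, "spikes", 1.0, seed = 7, n_spikes = 3))
  maxnorm <- apply(abs(sp), 1, max)
  expect_equal(sum(maxnorm >= 0.5), 3)
})

test_that("rendered run obeys the signal law", {
  # c = 0, zero motion, zero noise: every voxel time series constant
  run0 <- small_run(K = 8, asym = c(0, 0), base_c = 0)
  for (e in 1:2) {
    rng <- apply(run0$echoes[[e]], 1:3, function(v) diff(range(v)))
    expect_equal(max(rng), 0)
  }
  # signal strictly decreases with echo index inside the brain
  ph <- small_phantom()
  inb <- which(ph$brain_mask)
  m1 <- apply(run0$echoes[[1]], 1:3, mean)[inb]
  m2 <- apply(run0$echoes[[2]], 1:3, mean)[inb]
  expect_true(all(m2 < m1))
})

test_that("percent-change amplitude scales with TE between echoes", {
  run <- small_run(K = 40, asym = c(0, 0.5), base_c = 1e-4, noise_sd = 0)
  ph <- small_phantom(c(0, 0.5), 1e-4)
  hi <- ph$coupling_map > 0.5 * max(ph$coupling_map)
  amp <- function(e) {
    mat <- matrix(run$echoes[[e]], ncol = 40)[hi, ]
    mu <- rowMeans(mat)
    apply(100 * (mat - mu) / mu, 1, sd)
  }
  ratio <- amp(2) / amp(1)
  expect_equal(median(ratio), 30 / 13.7, tolerance = 0.03)
})

test_that("a pure one-voxel translation reproduces the shifted reference", {
  K <- 4
  mv <- matrix(0, K, 6)
  mv[3, 6] <- 3  # +3 mm = one voxel along z at frame 3
  run <- small_run(K = K, asym = c(0, 0), base_c = 0,
                   motion = motion_params(mv))
  e1 <- run$echoes[[1]]
  ref <- e1[, , , 1]
  moved <- e1[, , , 3]
  # movement of +1 voxel in z: moved[ , , k] == ref[ , , k - 1] interior
  expect_identical(moved[, , 5:14], ref[, , 4:13])
})

test_that("rendering is deterministic", {
  mv <- simulate_motion(6, "spikes", 0.5, seed = 2)
  a <- small_run(K = 6, noise_sd = 3, motion = mv, seed = 9)
  b <- small_run(K = 6, noise_sd = 3, motion = mv, seed = 9)
  expect_identical(a$echoes, b$echoes)
})

test_that("negative instantaneous R2* is clamped with a warning", {
  expect_warning(small_run(K = 12, base_c = 0.05), "clamped")
})
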