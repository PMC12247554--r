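# Framewise displacement, censoring, ROI FC, group stratification and
# the two-group permutation comparison.

test_that("framewise displacement combines translations and rotation arcs", {
  K <- 5
  m <- matrix(0, K, 6)
  fd0 <- framewise_displacement(motion_params(m))
  expect_equal(fd0$values, rep(0, K))
  # +0.1 mm jump on each translation axis at frame 3
  m1 <- m
  m1[3:K, 4:6] <- 0.1
  fd1 <- framewise_displacement(motion_params(m1))
  expect_equal(fd1$values[3], 0.3)
  expect_equal(fd1$values[4], 0)
  # +0.2 degree jump on one rotation axis: arc length at 50 mm
  m2 <- m
  m2[2:K, 1] <- 0.2
  fd2 <- framewise_displacement(motion_params(m2))
  expect_equal(fd2$values[2], 50 * 0.2 * pi / 180, tolerance = 1e-10)
  expect_equal(fd2$values[2], 0.17453, tolerance = 1e-4)
})

test_that("censoring keeps sub-threshold frames and flags unusable runs", {
  keep <- censor(c(0, 0.25, 0.1), threshold_mm = 0.2, min_frames = 2)
  expect_equal(as.logical(keep), c(TRUE, FALSE, TRUE))
  expect_true(attr(keep, "usable"))
  expect_false(attr(censor(rep(0.5, 30), 0.2), "usable"))
  # isolated motion spikes censor two frames each (backward differences)
  K <- 60
  truth <- simulate_motion(K, "spikes", 1.0, seed = 41, n_spikes = 3)
  fd <- framewise_displacement(truth)
  expect_equal(sum(!censor(fd, 0.2)), 6)
})

test_that("ROI extraction averages percent-change series per region", {
  dims <- c(8, 8, 6)
  K <- 10
  arr <- array(rnorm(prod(dims) * K), c(dims, K))
  one <- array(FALSE, dims); one[3, 4, 2] <- TRUE
  blk <- array(FALSE, dims); blk[5:6, 5:6, 3] <- TRUE
  arr[5:6, 5:6, 3, ] <- 7
  roi <- extract_roi_signals(arr, list(a = one, b = blk))
  expect_equal(roi$signals[, "a"], arr[3, 4, 2, ])
  expect_equal(roi$signals[, "b"], rep(7, K))
  expect_error(extract_roi_signals(arr, list(bad = array(FALSE, dims))),
               "empty ROI")
})

test_that("FC regression variants, Fisher z and degenerate pairs", {
  K <- 80
  set.seed(12)
  g <- simulate_gs_driver(K, 3, 0.1, 2)
  sig <- cbind(a = g + rnorm(K, sd = 0.5), b = g + rnorm(K, sd = 0.5),
               c = rnorm(K))
  # all-zero regressors leave FC untouched
  fc0 <- fc_with_regression(sig, matrix(0, K, 12))
  fcn <- fc_with_regression(sig)
  expect_equal(fc0$r_mat, fcn$r_mat)
  expect_equal(fcn$r_mat["a", "b"], cor(sig[, 1], sig[, 2]))
  # Fisher z closed form
  expect_equal(fisher_z(0.5), 0.54931, tolerance = 1e-5)
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  # identical residuals: r = 1 capped to finite z
  sig2 <- cbind(a = g, b = g)
  fc2 <- fc_with_regression(sig2)
  expect_true(is.finite(fc2$z_mat["a", "b"]))
  expect_gt(fc2$z_mat["a", "b"], 8)
  # regression removes a shared nuisance component
  fcg <- fc_with_regression(sig, cbind(g))
  expect_lt(abs(fcg$r_mat["a", "b"]), abs(fcn$r_mat["a", "b"]))
})

test_that("delta_fc differences and guards", {
  K <- 50
  set.seed(3)
  sig <- matrix(rnorm(K * 3), K, 3, dimnames = list(NULL, c("a", "b", "c")))
  fc <- fc_with_regression(sig)
  d <- delta_fc(fc, fc)
  expect_equal(max(abs(d$dz_mat)), 0)
  expect_equal(d$mean_dz, 0)
  sig2 <- sig[, 1:2]
  expect_error(delta_fc(fc, fc_with_regression(sig2)), "ROI set mismatch")
  fck <- fc_with_regression(sig, keep = c(rep(TRUE, 40), rep(FALSE, 10)))
  expect_error(delta_fc(fc, fck), "keep-mask")
})

test_that("aGS is the kept-frame standard deviation of the GS", {
  expect_equal(ags(rep(2, 30)), 0)
  gs <- c(rnorm(20), 8, 9)
  keep <- c(rep(TRUE, 20), FALSE, FALSE)
  expect_equal(ags(gs, keep), sd(gs[1:20]))
  expect_lt(ags(gs, keep), ags(gs))
})

test_that("four-group split enumerates the median rule", {
  fd <- c(0.1, 0.1, 0.3, 0.3)
  ag <- c(1, 2, 1, 2)
  sp <- four_group_split(fd, ag)
  expect_equal(as.character(sp$labels),
               c("lowFD_lowGS", "lowFD_highGS", "highFD_lowGS",
                 "highFD_highGS"))
  expect_equal(sum(table(sp$labels)), 4)
  # all-equal FD: strict > rule puts every run in the low-motion group
  sp2 <- four_group_split(rep(0.2, 6), c(1, 2, 3, 4, 5, 6))
  expect_true(all(grepl("^lowFD", sp2$labels)))
})

test_that("ANOVA F matches the sum-of-squares computation", {
  set.seed(9)
  g <- factor(rep(letters[1:4], each = 8))
  y <- rnorm(32) + rep(c(0, 0.5, 1, 1.5), each = 8)
  res <- group_effect_tests(y, g)
  gm <- tapply(y, g, mean)
  ssb <- sum(8 * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  f_brute <- (ssb / 3) / (ssw / 28)
  expect_equal(res$F, f_brute, tolerance = 1e-10)
  expect_equal(nrow(res$posthoc), 6)
  # strong separation is detected with small groups
  y2 <- rnorm(32, sd = 1) + rep(c(0, 0, 0, 3), each = 8)
  expect_lt(group_effect_tests(y2, g)$p, 1e-3)
})

test_that("null ANOVA p-values are approximately uniform", {
  ps <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    g <- factor(rep(1:4, each = 6))
    group_effect_tests(rnorm(24), g)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("two-group permutation test and Cohen's d closed form", {
  a <- c(1, 2, 3)
  b <- c(4, 5, 7)
  res <- two_group_permutation(a, b, n_perm = 2000, seed = 2)
  sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
  expect_equal(res$cohens_d, (mean(a) - mean(b)) / sp, tolerance = 1e-12)
  # identical groups: d = 0, p ~ 1
  same <- two_group_permutation(c(1, 1, 1), c(1, 1, 1), n_perm = 500, seed = 1)
  expect_equal(same$cohens_d, 0)
  expect_gt(same$p_two_sided, 0.99)
  # complete separation drives p to the boundary
  set.seed(5)
  x <- rnorm(20)
  y <- rnorm(20) + 5 * sd(x)
  far <- two_group_permutation(x, y, n_perm = 1e4, seed = 3)
  expect_equal(far$p_two_sided, 1 / (1 + 1e4))
})
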