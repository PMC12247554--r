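# Delta-m statistic, permutation nulls, empirical significance.

toy_motion <- function(values) motion_params(rbind(0, values))

test_that("delta_m subtracts, detrends, and rejects mismatches", {
  K <- 30
  set.seed(8)
  m1 <- toy_motion(matrix(rnorm(6 * (K - 1)), K - 1, 6))
  expect_equal(max(abs(delta_m(m1, m1))), 0)
  # common-mode motion cancels exactly
  m2 <- toy_motion(matrix(rnorm(6 * (K - 1)), K - 1, 6))
  common <- rbind(0, matrix(rnorm(6 * (K - 1)), K - 1, 6))
  m1c <- motion_params(unclass(as.matrix(m1)) + common)
  m2c <- motion_params(unclass(as.matrix(m2)) + common)
  expect_equal(unclass(delta_m(m2c, m1c)), unclass(delta_m(m2, m1)),
               tolerance = 1e-12)
  # columns are zero mean after detrending
  expect_lt(max(abs(colMeans(delta_m(m2, m1)))), 1e-10)
  bad <- m1
  attr(bad, "sign_convention") <- "other"
  expect_error(delta_m(m2, bad), "sign convention")
})

test_that("pearson_r matches the covariance formula and guards variance", {
  set.seed(2)
  x <- rnorm(40)
  y <- 0.3 * x + rnorm(40)
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), brute, tolerance = 1e-12)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(1, 40)), "zero-variance")
})

test_that("null distribution has n(n-1) samples and is centred for null data", {
  K <- 50
  mk <- function(s) {
    dm <- vapply(0:5, function(a) simulate_gs_driver(K, 3, 0.1, s + 7 * a),
                 numeric(K))
    colnames(dm) <- c("Rx", "Ry", "Rz", "Tx", "Ty", "Tz")
    list(dm = dm, gs = simulate_gs_driver(K, 3, 0.1, s + 1000))
  }
  runs <- lapply(1:6, function(i) mk(10 * i))
  null6 <- null_distribution(lapply(runs, `[[`, "dm"),
                             lapply(runs, `[[`, "gs"), "Tz")
  expect_length(null6, 6 * 5)
  expect_error(null_distribution(runs[1:2], runs[1:2], "Tz"), "at least 3")
  expect_equal(null_size(602), 361802)
  # independent GS and dm: null approximately symmetric about zero
  runs2 <- lapply(1:20, function(i) mk(777 + 13 * i))
  nl <- null_distribution(lapply(runs2, `[[`, "dm"),
                          lapply(runs2, `[[`, "gs"), "Ty")
  expect_lt(abs(mean(nl)), 2 * sd(nl) / sqrt(length(nl) / 4))
  # unequal lengths refuse unless reconciliation is requested
  short <- mk(1)
  short$dm <- short$dm[1:40, ]
  deltas <- c(lapply(runs[1:2], `[[`, "dm"), list(short$dm))
  gss <- lapply(runs[1:3], `[[`, "gs")
  expect_error(null_distribution(deltas, gss, "Tz"), "lengths differ")
  expect_length(null_distribution(deltas, gss, "Tz",
                                  reconcile_lengths = TRUE), 6)
})

test_that("empirical p-values and thresholds behave at the boundaries", {
  null <- seq(-0.5, 0.5, length.out = 400)
  res <- assess_significance(c(0, 0.9), null, alpha = 0.05, n_runs = 20)
  expect_gt(res$p_emp[1], 0.99)
  expect_equal(res$p_emp[2], 1 / 401)
  expect_true(res$significant[2])
  expect_false(res$significant[1])
  expect_equal(res$bonferroni_threshold_p, 0.0025)
})

test_that("a truly null axis rejects at close to the nominal rate", {
  # 200 runs of independent GS and dm; uncorrected empirical test at 5%
  K <- 60
  n <- 200
  gss <- lapply(1:n, function(i) simulate_gs_driver(K, 3, 0.1, 3 * i))
  dms <- lapply(1:n, function(i)
    matrix(simulate_gs_driver(K, 3, 0.1, 3 * i + 1), ncol = 1,
           dimnames = list(NULL, "Tz")))
  null <- null_distribution(dms, gss, "Tz")
  r_obs <- vapply(1:n, function(i) pearson_r(gss[[i]], dms[[i]][, 1]),
                  numeric(1))
  p <- vapply(r_obs, function(r)
    (1 + sum(abs(null) >= abs(r))) / (1 + length(null)), numeric(1))
  rate <- mean(p < 0.05)
  # binomial 95% band around 0.05 at n = 200
  expect_gt(rate, 0.05 - 1.96 * sqrt(0.05 * 0.95 / n))
  expect_lt(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / n))
})

test_that("the full chain drives r(dm, GS) toward 1 as noise vanishes", {
  # superior-weighted coupling, zero motion, zero noise: dm_Tz tracks the
  # driver almost perfectly (the small-signal limit of the two-echo model)
  run <- small_run(K = 40, asym = c(0, 0.5), noise_sd = 0)
  pr <- process_run(run)
  expect_gt(pearson_r(pr$dm[, "Tz"], pr$gs), 0.99)
})

test_that("bias_pipeline reports per-axis observed r, p and percentages", {
  K <- 60
  set.seed(31)
  mk <- function(i, biased) {
    gs <- simulate_gs_driver(K, 3, 0.1, 97 + i)
    dm <- matrix(rnorm(K * 6, sd = 0.01), K, 6,
                 dimnames = list(NULL, c("Rx", "Ry", "Rz", "Tx", "Ty", "Tz")))
    if (biased) dm[, "Tz"] <- dm[, "Tz"] + 0.05 * gs
    me1 <- motion_params(rbind(0, matrix(rnorm(6 * (K - 1), sd = 0.05),
                                         K - 1, 6)))
    list(dm = dm, gs = gs, me1 = me1)
  }
  runs <- lapply(1:10, mk, biased = TRUE)
  out <- bias_pipeline(runs, regress_e1_motion = FALSE)
  expect_equal(dim(out$r_obs), c(10L, 6L))
  expect_true(all(out$p_emp > 0 & out$p_emp <= 1))
  expect_length(out$null$Tz, 90)
  expect_gt(out$pct_significant["Tz"], 50)
  expect_lt(max(out$pct_significant[c("Rx", "Ry", "Rz", "Tx")]), 30)
  # e1 regression path runs and returns the same shape
  out2 <- bias_pipeline(runs, regress_e1_motion = TRUE)
  expect_equal(dim(out2$r_obs), dim(out$r_obs))
})
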