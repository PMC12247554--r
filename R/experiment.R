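# Experiment presets composing the modules end to end: per-run processing
# (register both echoes, mask, GS), the bias-power and null-calibration
# experiments, the FC-impact cohort experiment, and ground-truth
# validation. Every random stage consumes a seed derived from the master
# seed via derive_seed().

#' Default study conditions for synthetic runs
#'
#' Desk-scale mirror of a 3 T two-echo protocol: 32 x 32 x 24 grid at 3 mm
#' isotropic, K = 200 frames, TR = 3 s, TEs 13.7 / 30 ms, driver low-pass
#' 0.1 Hz, baseline coupling 1e-4 /ms (about 0.3% echo-2 global amplitude),
#' noise SD 7.5 (temporal SNR about 70 at the echo-2 brain mean).
#'
#' @return List of defaults used by the simulate/process helpers.
#' @export
study_conditions <- function() {
  list(grid_dims = c(32L, 32L, 24L), voxel_size_mm = c(3, 3, 3),
       brain_radii_mm = c(36, 42, 30), base_c = 1e-4,
       te_ms = c(13.7, 30), tr_s = 3, n_volumes = 200L,
       lowpass_hz = 0.1, noise_sd = 7.5)
}

#' Simulate one synthetic two-echo run
#'
#' Builds the phantom (with the requested coupling asymmetry and per-run
#' coupling scale), draws the GS driver and ground-truth motion from seeds
#' derived from the master seed, and renders both echoes.
#'
#' @param master_seed Master integer seed.
#' @param run_id Run index (used in seed derivation).
#' @param asym_coeffs Coupling asymmetry `(a_y, a_z)`.
#' @param coupling_scale Multiplies the coupling map (per-run GS amplitude).
#' @param motion_profile Passed to [simulate_motion()].
#' @param motion_amplitude Peak motion (mm / deg).
#' @param noise_sd Additive noise SD (NULL = study default).
#' @param n_volumes Number of frames (NULL = study default).
#' @param phantom Optional prebuilt phantom (overrides asym/scale).
#' @return A `multi_echo_run`.
#' @export
simulate_run <- function(master_seed, run_id = 1L, asym_coeffs = c(0.5, 0.5),
                         coupling_scale = 1, motion_profile = "drift",
                         motion_amplitude = 0.1, noise_sd = NULL,
                         n_volumes = NULL, phantom = NULL) {
  sc <- study_conditions()
  K <- n_volumes %||% sc$n_volumes
  if (is.null(phantom)) {
    phantom <- make_phantom(sc$grid_dims, sc$voxel_size_mm, sc$brain_radii_mm,
                            asym_coeffs = asym_coeffs, base_c = sc$base_c)
    phantom$coupling_map <- phantom$coupling_map * coupling_scale
  }
  cfg <- echo_config(sc$te_ms, sc$tr_s, K)
  truth <- list(
    motion = simulate_motion(K, motion_profile, motion_amplitude,
                             seed = derive_seed(master_seed, "motion", run_id)),
    gs_driver = simulate_gs_driver(K, sc$tr_s, sc$lowpass_hz,
                                   seed = derive_seed(master_seed, "driver",
                                                      run_id)),
    noise_sd = noise_sd %||% sc$noise_sd,
    seed = derive_seed(master_seed, "noise", run_id))
  render_run(phantom, cfg, truth)
}

#' Process one two-echo run
#'
#' Registers both echoes to their first volume, forms the brain mask from
#' the mean unregistered echo-1 volume, computes the percent-change GS from
#' the registered echo-2 data, the dm matrix, FD (from e1 estimates) and
#' the censoring mask. Optionally also returns GS beta maps computed from
#' the unregistered percent-change data of each echo, the per-echo
#' reference volumes, and ROI-average signals from the registered echo-2
#' percent-change data.
#'
#' @param run A `multi_echo_run` (or list of two 4-D arrays plus
#'   `voxel_size_mm`).
#' @param cfg A [deriv_config()].
#' @param compute_beta Also compute unregistered-data beta maps and keep
#'   the reference volumes. Two forms are stored: `beta_e*` in percent-change
#'   units over the brain mask (the map form used for visualization), and
#'   `beta_raw_e*` in raw intensity units per unit GS over the full grid
#'   (the form whose inner products with the derivative images quantitatively
#'   reproduce the registration estimator, which sees raw intensities at
#'   every voxel).
#' @param roi_masks Optional named list of ROI masks for FC analysis.
#' @param fd_threshold_mm Censoring threshold.
#' @return List with `me1`, `me2`, `dm`, `gs`, `mask`, `fd`, `keep`,
#'   `mean_fd`, `ags`, and optionally `beta_e1`, `beta_e2`, `ref_e1`,
#'   `ref_e2`, `roi`.
#' @export
process_run <- function(run, cfg = deriv_config(), compute_beta = FALSE,
                        roi_masks = NULL, fd_threshold_mm = 0.2) {
  vox <- run$voxel_size_mm %||% c(3, 3, 3)
  e1 <- run$echoes[[1]]
  e2 <- run$echoes[[2]]
  mask <- automask(apply(e1, 1:3, mean), clip_frac = 0.5)

  me1 <- register_run(e1, 1L, cfg, vox)
  reg2 <- register_run(e2, 1L, cfg, vox, return_registered = TRUE)
  me2 <- reg2$params

  norm2 <- percent_change(reg2$registered, mask)
  gs <- global_signal(norm2, mask)
  dm <- delta_m(me2, me1)

  fd <- framewise_displacement(me1)
  keep <- censor(fd, fd_threshold_mm)

  out <- list(me1 = me1, me2 = me2, dm = dm, gs = gs, mask = mask,
              fd = fd, keep = keep, mean_fd = fd$mean_fd,
              ags = ags(gs, keep))
  if (compute_beta) {
    out$beta_e1 <- beta_map(percent_change(e1, mask), gs, mask, 1L)
    out$beta_e2 <- beta_map(percent_change(e2, mask), gs, mask, 2L)
    dims <- dim(e1)[1:3]
    raw_beta <- function(echo4d, idx) {
      v <- beta_map(matrix(echo4d, ncol = dim(echo4d)[4]), as.numeric(gs))
      list(values = array(v$values, dims), echo_index = idx)
    }
    out$beta_raw_e1 <- raw_beta(e1, 1L)
    out$beta_raw_e2 <- raw_beta(e2, 2L)
    out$ref_e1 <- e1[, , , 1]
    out$ref_e2 <- e2[, , , 1]
  }
  if (!is.null(roi_masks))
    out$roi <- extract_roi_signals(norm2, roi_masks)
  out
}

#' Bias power / specificity experiment
#'
#' Simulates `n_runs` two-echo runs with the given coupling asymmetry and
#' low drift motion, processes each, and runs the bias detection with and
#' without e1 motion regression.
#'
#' @param n_runs Number of runs (default 20).
#' @param asym_coeffs Coupling asymmetry `(a_y, a_z)`.
#' @param master_seed Master seed.
#' @param motion_amplitude Drift amplitude (mm / deg).
#' @param compute_beta Keep beta maps / references for the spatial
#'   decomposition.
#' @param n_volumes Frames per run (NULL = study default).
#' @param alpha Family-wise level.
#' @return List with `processed` (per-run summaries), `truths` (per-run
#'   ground truth), `bias` and `bias_e1reg` (`bias_result`s).
#' @export
run_bias_experiment <- function(n_runs = 20, asym_coeffs = c(0.5, 0.5),
                                master_seed = 1L, motion_amplitude = 0.1,
                                compute_beta = FALSE, n_volumes = NULL,
                                alpha = 0.05) {
  processed <- vector("list", n_runs)
  truths <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    run <- simulate_run(master_seed, i, asym_coeffs = asym_coeffs,
                        motion_profile = "drift",
                        motion_amplitude = motion_amplitude,
                        n_volumes = n_volumes)
    truths[[i]] <- run$truth
    processed[[i]] <- process_run(run, compute_beta = compute_beta)
  }
  list(processed = processed, truths = truths,
       bias = bias_pipeline(processed, FALSE, alpha),
       bias_e1reg = bias_pipeline(processed, TRUE, alpha))
}

#' Null calibration of the uncorrected empirical test
#'
#' Generates cohorts of independently drawn GS and dm series (no coupling,
#' so the null hypothesis holds by construction), runs the empirical-null
#' test per run at uncorrected alpha, and reports the rejection rate over
#' all evaluations.
#'
#' @param n_runs Runs per cohort (null size `n_runs * (n_runs - 1)`).
#' @param n_reps Number of independent cohorts.
#' @param master_seed Master seed.
#' @param alpha Uncorrected level.
#' @param K Series length.
#' @return List with `rejection_rate_pct`, `n_evaluations`.
#' @export
run_null_calibration <- function(n_runs = 30, n_reps = 17, master_seed = 1L,
                                 alpha = 0.05, K = 200) {
  sc <- study_conditions()
  n_rej <- 0L
  n_tot <- 0L
  for (rep in seq_len(n_reps)) {
    gss <- lapply(seq_len(n_runs), function(i)
      simulate_gs_driver(K, sc$tr_s, sc$lowpass_hz,
                         derive_seed(master_seed, "cal-gs", rep * 1000 + i)))
    dms <- lapply(seq_len(n_runs), function(i)
      matrix(simulate_gs_driver(K, sc$tr_s, sc$lowpass_hz,
                                derive_seed(master_seed, "cal-dm",
                                            rep * 1000 + i)),
             ncol = 1, dimnames = list(NULL, "Tz")))
    null <- numeric(n_runs * (n_runs - 1))
    k <- 0L
    for (i in seq_len(n_runs)) for (j in seq_len(n_runs)) {
      if (i == j) next
      null[k <- k + 1L] <- pearson_r(gss[[i]], dms[[j]][, 1])
    }
    r_obs <- vapply(seq_len(n_runs), function(i)
      pearson_r(gss[[i]], dms[[i]][, 1]), numeric(1))
    p <- vapply(r_obs, function(r)
      (1 + sum(abs(null) >= abs(r))) / (1 + length(null)), numeric(1))
    n_rej <- n_rej + sum(p < alpha)
    n_tot <- n_tot + n_runs
  }
  list(rejection_rate_pct = 100 * n_rej / n_tot, n_evaluations = n_tot)
}

# Column subsets of the 12-column motion regressor matrix.
regressor_subset <- function(X12, which = c("all", "TyTz", "exclTyTz")) {
  which <- match.arg(which)
  cols <- switch(which,
                 all = 1:12,
                 TyTz = c(5, 6, 11, 12),
                 exclTyTz = c(1:4, 7:10))
  X12[, cols, drop = FALSE]
}

#' FC-impact cohort experiment
#'
#' Simulates a cohort of runs spanning two groups — "young-like" (high
#' coupling scale, low motion) and "old-like" (low coupling scale, higher
#' motion) — processes each run, extracts ROI signals from the registered
#' echo-2 data, and computes the ROI-ROI FC after e1 vs e2 motion
#' regression (full 12-column set, the Ty/Tz-only subset and the
#' excluding-Ty/Tz subset), with censoring applied before regression and
#' the same keep mask for every variant. Returns per-run summaries, the
#' four-group stratification, the ANOVA/post-hoc tests and the young-like
#' vs old-like comparison of mean dz.
#'
#' @param n_runs Total runs (half per group; default 24).
#' @param master_seed Master seed.
#' @param asym_coeffs Coupling asymmetry.
#' @param n_volumes Frames per run (NULL = study default).
#' @param n_perm Permutations for the two-group test.
#' @return List with `runs` (data frame), `split`, `tests`, `group_means`,
#'   `cohort` (two-group permutation + Cohen's d on mean dz).
#' @export
run_fc_experiment <- function(n_runs = 24, master_seed = 1L,
                              asym_coeffs = c(0.5, 0.5), n_volumes = NULL,
                              n_perm = 1e4) {
  sc <- study_conditions()
  half <- n_runs %/% 2
  young <- c(rep(TRUE, half), rep(FALSE, n_runs - half))
  roi_masks <- default_roi_masks()
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    pseed <- derive_seed(master_seed, "fc-params", i)
    pars <- with_seed(pseed, {
      # GS amplitude spans a wide (log-uniform) range within each group, as
      # in resting-state cohorts, so the FD-by-aGS strata differ in aGS and
      # not only in motion; motion bands overlap slightly across groups
      if (young[i]) list(scale = exp(runif(1, log(0.8), log(3.0))),
                         amp = runif(1, 0.06, 0.14))
      else list(scale = exp(runif(1, log(0.25), log(1.0))),
                amp = runif(1, 0.15, 0.5))
    })
    run <- simulate_run(master_seed, i, asym_coeffs = asym_coeffs,
                        coupling_scale = pars$scale,
                        motion_profile = "mixed", motion_amplitude = pars$amp,
                        n_volumes = n_volumes)
    pr <- process_run(run, roi_masks = roi_masks)
    X1 <- derivative_regressors(pr$me1)
    X2 <- derivative_regressors(pr$me2)
    keep <- pr$keep
    fc_var <- function(X, set) fc_with_regression(pr$roi, X, keep, set)
    fc_e1 <- fc_var(X1, "e1")
    fc_e2 <- fc_var(X2, "e2")
    d_full <- delta_fc(fc_e2, fc_e1)
    d_excl <- delta_fc(fc_var(regressor_subset(X2, "exclTyTz"),
                              "e2_excl_TyTz"),
                       fc_var(regressor_subset(X1, "exclTyTz"),
                              "e1_excl_TyTz"))
    d_tytz <- delta_fc(fc_var(regressor_subset(X2, "TyTz"), "e2_TyTz_only"),
                       fc_var(regressor_subset(X1, "TyTz"), "e1_TyTz_only"))
    ut <- upper.tri(fc_e1$z_mat)
    rows[[i]] <- data.frame(
      run = i, young_like = young[i], coupling_scale = pars$scale,
      motion_amplitude = pars$amp, mean_fd = pr$mean_fd, ags = pr$ags,
      n_kept = sum(keep),
      mean_dz = d_full$mean_dz, mean_dr = d_full$mean_dr,
      mean_dz_excl_tytz = d_excl$mean_dz, mean_dz_tytz_only = d_tytz$mean_dz,
      mean_z_e1 = mean(fc_e1$z_mat[ut]), mean_z_e2 = mean(fc_e2$z_mat[ut]))
  }
  runs <- do.call(rbind, rows)
  split <- four_group_split(runs$mean_fd, runs$ags)
  tests <- group_effect_tests(runs$mean_dz, split)
  group_means <- tapply(runs$mean_dz, split$labels, mean)
  cohort <- two_group_permutation(runs$mean_dz[runs$young_like],
                                  runs$mean_dz[!runs$young_like],
                                  n_perm = n_perm,
                                  seed = derive_seed(master_seed, "fc-perm"))
  list(runs = runs, split = split, tests = tests, group_means = group_means,
       cohort = cohort)
}

#' Default ROI set for the FC experiment
#'
#' Four 12-mm spherical ROIs placed well inside the phantom brain
#' (posterior, anterior, left and right of centre), all with positive GS
#' coupling so FC between them is GS-coupled.
#'
#' @param dims Grid dimensions (study default).
#' @param voxel_size_mm Voxel size.
#' @return Named list of logical masks.
#' @export
default_roi_masks <- function(dims = study_conditions()$grid_dims,
                              voxel_size_mm = study_conditions()$voxel_size_mm) {
  make_roi_masks(dims, voxel_size_mm,
                 centers_mm = list(post = c(0, 21, 9), ant = c(0, -21, 9),
                                   left = c(-18, 0, 12), right = c(18, 0, 12)))
}

#' Validate processed runs against ground truth
#'
#' Per-axis RMSE of the echo-1 motion estimates against the true motion,
#' correlation of the recovered GS with the true driver, and
#' bias-detection confusion counts when a `bias_result` and the set of
#' truly biased axes are supplied.
#'
#' @param processed List of per-run [process_run()] outputs.
#' @param truths List of per-run ground truth (from the simulator).
#' @param bias Optional `bias_result`.
#' @param biased_axes Optional character vector of truly biased axes.
#' @return List with `rmse` (runs x 6), `gs_cor` (per run), and optionally
#'   `confusion`.
#' @export
validate_against_truth <- function(processed, truths, bias = NULL,
                                   biased_axes = NULL) {
  stopifnot(length(processed) == length(truths))
  n <- length(processed)
  rmse <- t(vapply(seq_len(n), function(i) {
    err <- unclass(as.matrix(processed[[i]]$me1)) -
      unclass(as.matrix(truths[[i]]$motion))
    sqrt(colMeans(err^2))
  }, numeric(6)))
  colnames(rmse) <- axis_names()
  gs_cor <- vapply(seq_len(n), function(i)
    pearson_r(as.numeric(processed[[i]]$gs),
              detrend_quadratic(truths[[i]]$gs_driver)), numeric(1))
  out <- list(rmse = rmse, gs_cor = gs_cor)
  if (!is.null(bias) && !is.null(biased_axes)) {
    sig <- colMeans(bias$significant) > 0.5
    truly <- axis_names() %in% biased_axes
    out$confusion <- c(tp = sum(sig & truly), fp = sum(sig & !truly),
                       fn = sum(!sig & truly), tn = sum(!sig & !truly))
  }
  out
}
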