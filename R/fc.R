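# Downstream effect of biased motion regressors on ROI-ROI functional
# connectivity: framewise displacement, censoring, motion regression with
# e1 vs e2 parameter sets (or Ty/Tz subsets), Fisher-z FC, dz/dr, GS
# amplitude, four-group stratification with ANOVA and post-hoc t-tests,
# and a generic two-group permutation comparison with Cohen's d.

#' Framewise displacement
#'
#' `FD_t = sum |diff translations| + radius * sum |diff rotations in rad|`
#' (backward differences; rotations converted from degrees to arc length at
#' `radius_mm`). The first element is 0.
#'
#' @param m `motion_params` (or K x 6 matrix, columns Rx Ry Rz Tx Ty Tz).
#' @param radius_mm Head radius for the rotation arc length (default 50).
#' @return List with `values` (length-K, mm), `radius_mm`, `mean_fd`.
#' @export
framewise_displacement <- function(m, radius_mm = 50) {
  m <- unclass(as.matrix(m))
  stopifnot(ncol(m) == 6, nrow(m) >= 2)
  d <- abs(diff(m))
  fd <- c(0, rowSums(d[, 4:6, drop = FALSE]) +
            radius_mm * rowSums(d[, 1:3, drop = FALSE]) * pi / 180)
  list(values = fd, radius_mm = radius_mm, mean_fd = mean(fd))
}

#' Motion censoring
#'
#' Keep frames with `FD <= threshold_mm`. Runs retaining fewer than
#' `min_frames` frames are flagged unusable.
#'
#' @param fd [framewise_displacement()] result (or numeric FD vector).
#' @param threshold_mm Censoring threshold (default 0.2 mm).
#' @param min_frames Minimum kept frames before the run is unusable.
#' @return Logical keep mask with attribute `usable`.
#' @export
censor <- function(fd, threshold_mm = 0.2, min_frames = 20L) {
  stopifnot(threshold_mm > 0)
  v <- if (is.list(fd)) fd$values else fd
  keep <- v <= threshold_mm
  structure(keep, usable = sum(keep) >= min_frames)
}

#' ROI-average signals
#'
#' Spatial mean of the percent-change data over each ROI mask, per frame.
#'
#' @param norm4d 4-D percent-change array.
#' @param roi_masks Named list of 3-D logical arrays (each nonempty).
#' @return List with `signals` (K x R matrix, columns named), `roi_names`.
#' @export
extract_roi_signals <- function(norm4d, roi_masks) {
  stopifnot(length(roi_masks) >= 1)
  K <- dim(norm4d)[4]
  mat <- matrix(norm4d, ncol = K)
  nms <- names(roi_masks) %||% paste0("ROI", seq_along(roi_masks))
  sig <- vapply(seq_along(roi_masks), function(i) {
    idx <- which(as.logical(roi_masks[[i]]))
    if (length(idx) == 0) stop("empty ROI: ", nms[i])
    colMeans(mat[idx, , drop = FALSE])
  }, numeric(K))
  colnames(sig) <- nms
  list(signals = sig, roi_names = nms, roi_masks = roi_masks)
}

#' ROI-ROI FC after nuisance regression
#'
#' Regresses the given regressors out of each ROI column on kept frames,
#' then computes pairwise Pearson correlations and Fisher z. `|r|` is
#' capped at `1 - 1e-7` before `atanh`.
#'
#' @param roi [extract_roi_signals()] result (or K x R matrix).
#' @param regressors K x p matrix (may have zero columns for no
#'   regression).
#' @param keep Logical keep mask (default all frames).
#' @param regressor_set Label stored on the result.
#' @return An `fc_result`: list with `r_mat`, `z_mat`, `regressor_set`,
#'   `keep`.
#' @export
fc_with_regression <- function(roi, regressors = NULL, keep = NULL,
                               regressor_set = "none") {
  sig <- if (is.list(roi)) roi$signals else roi
  K <- nrow(sig)
  R <- ncol(sig)
  stopifnot(R >= 2)
  keep <- keep %||% rep(TRUE, K)
  p <- if (is.null(regressors)) 0 else ncol(regressors)
  if (sum(keep) <= p + 2)
    stop("too few kept frames (", sum(keep), ") for ", p, " regressors")
  res <- sig
  if (!is.null(regressors) && ncol(regressors) > 0 &&
      any(regressors[keep, ] != 0)) {
    for (j in seq_len(R))
      res[, j] <- nuisance_regress(sig[, j], regressors, keep)
  } else {
    res[!keep, ] <- NA_real_
  }
  r_mat <- stats::cor(res[keep, , drop = FALSE])
  z_mat <- fisher_z(r_mat)  # |r| capped, so the diagonal stays finite
  structure(list(r_mat = r_mat, z_mat = z_mat,
                 regressor_set = regressor_set, keep = keep),
            class = "fc_result")
}

#' FC difference between two regression variants
#'
#' Element-wise e2 - e1 differences of the r and z matrices, and the mean
#' over the off-diagonal upper triangle.
#'
#' @param fc_e2,fc_e1 `fc_result` objects with identical ROI sets and keep
#'   masks.
#' @return List with `dz_mat`, `dr_mat`, `mean_dz`, `mean_dr`.
#' @export
delta_fc <- function(fc_e2, fc_e1) {
  if (!identical(dim(fc_e2$r_mat), dim(fc_e1$r_mat)) ||
      !identical(colnames(fc_e2$r_mat), colnames(fc_e1$r_mat)))
    stop("ROI set mismatch between FC results")
  if (!identical(fc_e2$keep, fc_e1$keep))
    stop("keep-mask mismatch between FC results")
  dr <- fc_e2$r_mat - fc_e1$r_mat
  dz <- fisher_z(fc_e2$r_mat) - fisher_z(fc_e1$r_mat)
  ut <- upper.tri(dr)
  list(dz_mat = dz, dr_mat = dr, mean_dz = mean(dz[ut]), mean_dr = mean(dr[ut]))
}

#' Global-signal amplitude
#'
#' Sample standard deviation of the global signal over kept (uncensored)
#' frames.
#'
#' @param gs Global-signal vector.
#' @param keep Logical keep mask (default all).
#' @return Scalar aGS.
#' @export
ags <- function(gs, keep = NULL) {
  gs <- as.numeric(gs)
  keep <- keep %||% rep(TRUE, length(gs))
  stopifnot(sum(keep) >= 2)
  sd(gs[keep])
}

#' Four-group stratification by motion and GS amplitude
#'
#' Runs are first split by mean FD (strictly greater than the median ->
#' high motion), then each FD group is split by aGS (strictly greater than
#' the within-group median -> high aGS). Ties fall to "low".
#'
#' @param mean_fd Numeric per-run mean FD.
#' @param ags_vals Numeric per-run aGS.
#' @return List with `labels` (factor with levels lowFD_highGS, lowFD_lowGS,
#'   highFD_highGS, highFD_lowGS), `fd_median`, `ags_medians`.
#' @export
four_group_split <- function(mean_fd, ags_vals) {
  n <- length(mean_fd)
  stopifnot(length(ags_vals) == n, n >= 4)
  fd_med <- median(mean_fd)
  high_fd <- mean_fd > fd_med
  ags_med <- c(low = NA_real_, high = NA_real_)
  labels <- character(n)
  for (g in c(FALSE, TRUE)) {
    idx <- which(high_fd == g)
    med <- median(ags_vals[idx])
    ags_med[if (g) "high" else "low"] <- med
    hi_gs <- ags_vals[idx] > med
    labels[idx] <- paste0(if (g) "highFD" else "lowFD",
                          ifelse(hi_gs, "_highGS", "_lowGS"))
  }
  list(labels = factor(labels, levels = c("lowFD_highGS", "lowFD_lowGS",
                                          "highFD_highGS", "highFD_lowGS")),
       fd_median = fd_med, ags_medians = ags_med)
}

#' Group-effect tests on per-run mean dz
#'
#' One-way ANOVA across the four FD-by-aGS groups plus all pairwise
#' two-sample t-tests (two-sided, pooled variance).
#'
#' @param mean_dz Numeric per-run values.
#' @param split [four_group_split()] result (or a factor).
#' @return List with `F`, `p`, `anova` (the aov fit) and `posthoc` (data
#'   frame of the 6 pairwise tests).
#' @export
group_effect_tests <- function(mean_dz, split) {
  g <- if (is.list(split)) split$labels else split
  g <- droplevels(as.factor(g))
  if (any(table(g) < 2)) stop("each group needs at least 2 runs")
  fit <- aov(mean_dz ~ g)
  s <- summary(fit)[[1]]
  combs <- utils::combn(levels(g), 2)
  posthoc <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    tt <- t.test(mean_dz[g == a], mean_dz[g == b], var.equal = TRUE)
    data.frame(group_a = a, group_b = b, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               mean_a = unname(tt$estimate[1]), mean_b = unname(tt$estimate[2]))
  }))
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1], anova = fit,
       posthoc = posthoc)
}

#' Two-group permutation test with Cohen's d
#'
#' Statistic: difference of group means. Two-sided p with the add-one
#' estimator `(1 + #{|perm| >= |obs|}) / (1 + n_perm)`; effect size is
#' Cohen's d with pooled SD.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @param n_perm Number of random permutations (>= 100).
#' @param seed Integer seed.
#' @return List with `p_two_sided`, `cohens_d`, `observed`.
#' @export
two_group_permutation <- function(a, b, n_perm = 1e4, seed = 1L) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2, n_perm >= 100)
  obs <- mean(a) - mean(b)
  pooled <- c(a, b)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample(na + nb, na)
    mean(pooled[idx]) - mean(pooled[-idx])
  }, numeric(1)))
  p <- (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  d <- if (sp == 0) 0 else obs / sp
  list(p_two_sided = p, cohens_d = d, observed = obs)
}

#' Spherical ROI masks in phantom space
#'
#' Generator-defined spherical label regions (default 12 mm diameter)
#' centred at the given mm offsets from the grid centre; stand-ins for
#' seed-sphere ROIs in real space.
#'
#' @param dims Grid dimensions.
#' @param voxel_size_mm Voxel size.
#' @param centers_mm Named list of 3-vectors (mm offsets from grid centre).
#' @param diameter_mm Sphere diameter (default 12).
#' @return Named list of 3-D logical arrays.
#' @export
make_roi_masks <- function(dims, voxel_size_mm = c(3, 3, 3), centers_mm,
                           diameter_mm = 12) {
  ctr <- (dims - 1) / 2
  x <- (seq_len(dims[1]) - 1 - ctr[1]) * voxel_size_mm[1]
  y <- (seq_len(dims[2]) - 1 - ctr[2]) * voxel_size_mm[2]
  z <- (seq_len(dims[3]) - 1 - ctr[3]) * voxel_size_mm[3]
  X <- array(x, dims)
  Y <- array(rep(y, each = dims[1]), dims)
  Z <- array(rep(z, each = dims[1] * dims[2]), dims)
  r <- diameter_mm / 2
  lapply(centers_mm, function(cc)
    (X - cc[1])^2 + (Y - cc[2])^2 + (Z - cc[3])^2 <= r^2)
}
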