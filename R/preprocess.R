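# Shared preprocessing: brain masking, percent-change normalization,
# global-signal extraction, quadratic detrending, nuisance regression and
# the 12-column motion regressor matrix.

#' Automatic brain mask
#'
#' Thresholds the mean volume at `clip_frac` times a robust maximum (the
#' 99th percentile), keeps the largest 6-connected component and fills
#' interior holes (background components not touching the grid border).
#'
#' @param mean_vol 3-D numeric array (typically the temporal mean volume).
#' @param clip_frac Threshold fraction in (0, 1).
#' @return List with `values` (3-D logical array) and `n_voxels`.
#' @export
automask <- function(mean_vol, clip_frac = 0.5) {
  stopifnot(clip_frac > 0, clip_frac < 1)
  dims <- dim(mean_vol)
  thr <- clip_frac * quantile(mean_vol, 0.99, names = FALSE)
  fg <- mean_vol > thr
  if (!any(fg)) stop("empty mask: no voxels above threshold")
  lab <- array(cpp_label_components(fg, dims), dims)
  keep <- which.max(tabulate(lab[lab > 0]))
  mask <- lab == keep
  # fill holes: background components not touching the border are interior
  bg_lab <- array(cpp_label_components(!mask, dims), dims)
  border <- unique(c(bg_lab[c(1, dims[1]), , ], bg_lab[, c(1, dims[2]), ],
                     bg_lab[, , c(1, dims[3])]))
  border <- border[border > 0]
  mask[bg_lab > 0 & !(bg_lab %in% border)] <- TRUE
  list(values = mask, n_voxels = sum(mask))
}

#' Percent-signal-change normalization
#'
#' `out(v, t) = 100 * (x(v, t) - mean_t x(v)) / mean_t x(v)` inside the
#' mask, 0 outside. Voxels with zero temporal mean inside the mask are set
#' to 0 and counted in the `n_zero_mean` attribute.
#'
#' @param run4d 4-D numeric array.
#' @param mask Brain mask from [automask()] (or a 3-D logical array).
#' @return 4-D array of percent changes, attribute `n_zero_mean`.
#' @export
percent_change <- function(run4d, mask) {
  m <- if (is.list(mask)) mask$values else mask
  dims <- dim(run4d)
  K <- dims[4]
  mat <- matrix(run4d, ncol = K)  # voxels x time
  idx <- which(as.logical(m))
  mu <- rowMeans(mat[idx, , drop = FALSE])
  out <- matrix(0, nrow(mat), K)
  ok <- mu != 0
  out[idx[ok], ] <- 100 * (mat[idx[ok], , drop = FALSE] - mu[ok]) / mu[ok]
  res <- array(out, dims)
  attr(res, "n_zero_mean") <- sum(!ok)
  res
}

#' Global signal from normalized data
#'
#' Spatial mean of the percent-change data over in-mask voxels per frame,
#' then quadratic detrending ([detrend_quadratic()]).
#'
#' @param norm4d 4-D percent-change array.
#' @param mask Brain mask.
#' @param detrend Apply quadratic detrending (default TRUE).
#' @return Numeric length-K vector (class `global_signal`, attribute
#'   `detrended`).
#' @export
global_signal <- function(norm4d, mask, detrend = TRUE) {
  m <- if (is.list(mask)) mask$values else mask
  K <- dim(norm4d)[4]
  mat <- matrix(norm4d, ncol = K)
  gs <- colMeans(mat[as.logical(m), , drop = FALSE])
  if (detrend) gs <- detrend_quadratic(gs)
  structure(gs, detrended = detrend, class = "global_signal")
}

#' Remove mean, linear and quadratic trends
#'
#' Least-squares residual on the basis `{1, t, t^2}` with `t` centred and
#' scaled to `[-1, 1]`. Idempotent; applied identically to the global
#' signal and to motion-parameter columns.
#'
#' @param series Numeric vector, length >= 4 (a matrix is detrended by
#'   column).
#' @return Detrended vector (or matrix).
#' @export
detrend_quadratic <- function(series) {
  if (is.matrix(series)) return(apply(series, 2, detrend_quadratic))
  K <- length(series)
  stopifnot(K >= 4)
  t <- seq(-1, 1, length.out = K)
  X <- cbind(1, t, t^2)
  as.numeric(series - X %*% qr.coef(qr(X), series))
}

#' Nuisance regression
#'
#' Ordinary least squares of `target` on `regressors` (an intercept is
#' always included), restricted to kept frames. Returns the full-length
#' residual vector with `NA` at censored frames, so downstream correlations
#' drop censored frames. Collinear regressor columns are dropped with a
#' warning.
#'
#' @param target Numeric length-K vector.
#' @param regressors K x p numeric matrix (finite).
#' @param censor_keep Optional logical length-K keep mask.
#' @return Numeric length-K vector (NA at censored frames).
#' @export
nuisance_regress <- function(target, regressors, censor_keep = NULL) {
  K <- length(target)
  regressors <- as.matrix(regressors)
  stopifnot(nrow(regressors) == K, all(is.finite(regressors)))
  keep <- censor_keep %||% rep(TRUE, K)
  X <- cbind(`(intercept)` = 1, regressors)[keep, , drop = FALSE]
  if (ncol(X) >= sum(keep))
    stop("more regressors (", ncol(X) - 1, ") than kept frames (",
         sum(keep), ")")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    warning("dropping collinear regressor column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  out <- rep(NA_real_, K)
  out[keep] <- qr.resid(qx, target[keep])
  out
}

#' Motion regressors with first derivatives
#'
#' Columns 1-6 are the six motion parameters; columns 7-12 their backward
#' differences (first element 0).
#'
#' @param m A `motion_params` object (or K x 6 matrix), K >= 2.
#' @return K x 12 numeric matrix.
#' @export
derivative_regressors <- function(m) {
  m <- unclass(as.matrix(m))
  stopifnot(ncol(m) == 6, nrow(m) >= 2)
  d <- rbind(0, diff(m))
  out <- cbind(m, d)
  colnames(out) <- c(axis_names(), paste0("d", axis_names()))
  out
}
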