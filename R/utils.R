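#' @useDynLib gsbias, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor lm median quantile qt rnorm runif sd aov t.test
#' @importFrom utils write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Derive a per-stage seed from a master seed
#'
#' Deterministic integer hash of (master seed, stage name, run id), kept
#' below 2^31 so it is a valid R seed. Used so that every random stage of an
#' experiment consumes its own reproducible seed.
#'
#' @param master Integer master seed.
#' @param stage Character stage name.
#' @param run_id Integer run index (default 0).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, stage, run_id = 0L) {
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  h <- (h * 131 + as.double(run_id) * 2654435761) %% 2147483647
  as.integer(h)
}

axis_names <- function() c("Rx", "Ry", "Rz", "Tx", "Ty", "Tz")

#' Fisher z-transform of a correlation
#'
#' `atanh(r)` with `|r|` capped at `1 - 1e-7` so that perfectly correlated
#' (degenerate) pairs stay finite.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  atanh(r)
}
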