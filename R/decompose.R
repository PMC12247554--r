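# Spatial-map decomposition of r(dm, GS): GS beta-coefficient maps,
# registration derivative images, and the approximation
#   r(dm, GS) ~ (||gs|| / ||dm||) *
#               (beta_e2' d_e2 / ||d_e2||^2 - beta_e1' d_e1 / ||d_e1||^2)
# whose element-wise product maps explain where the bias comes from.

#' GS beta-coefficient map
#'
#' Per-voxel projection of the percent-change data onto the global signal:
#' `beta(v) = Y(v, ) . gs / ||gs||^2`, computed (by default) from the
#' unregistered data. Units: percent change per unit GS.
#'
#' @param norm4d 4-D percent-change array (or an N x K matrix of in-mask
#'   voxel series).
#' @param gs Global-signal vector, nonzero norm.
#' @param mask Brain mask (required when `norm4d` is 4-D).
#' @param echo_index Echo label stored on the result.
#' @return List with `values` (3-D array, zero outside mask; or N-vector
#'   when the input was a matrix), `echo_index`.
#' @export
beta_map <- function(norm4d, gs, mask = NULL, echo_index = NA_integer_) {
  gs <- as.numeric(gs)
  g2 <- sum(gs^2)
  if (g2 == 0) stop("zero-norm global signal")
  if (is.matrix(norm4d)) {
    return(list(values = as.numeric(norm4d %*% gs) / g2,
                echo_index = echo_index))
  }
  m <- if (is.list(mask)) mask$values else mask
  stopifnot(!is.null(m))
  dims <- dim(norm4d)[1:3]
  Y <- matrix(norm4d, ncol = dim(norm4d)[4])[as.logical(m), , drop = FALSE]
  out <- array(0, dims)
  out[as.logical(m)] <- as.numeric(Y %*% gs) / g2
  list(values = out, echo_index = echo_index)
}

#' Approximate r(dm, GS) from spatial maps
#'
#' Computes the scale factor `||gs|| / ||dm||`, the per-echo inner products
#' `beta' d / ||d||^2`, the element-wise product maps
#' `beta (*) d / ||d||^2` for each echo and their e2 - e1 difference, the
#' resulting approximation to r(dm, GS), and the direct Pearson r for
#' comparison. Norms and inner products are taken over in-mask voxels.
#'
#' @param beta_e1,beta_e2 [beta_map()] results (3-D values).
#' @param d_e1,d_e2 [spatial_derivative()] results for one motion axis.
#' @param gs Global-signal vector.
#' @param dm_col Numeric vector: the dm column for the same motion axis.
#' @param mask Brain mask.
#' @return A `map_decomposition`: list with `product_e1`, `product_e2`,
#'   `product_diff` (3-D arrays), `axis`, `approx_r`, `direct_r`,
#'   `scale_factor`, `term_e1`, `term_e2`.
#' @export
approx_r <- function(beta_e1, beta_e2, d_e1, d_e2, gs, dm_col, mask) {
  m <- as.logical(if (is.list(mask)) mask$values else mask)
  gs <- as.numeric(gs)
  dm_col <- as.numeric(dm_col)
  ok <- is.finite(gs) & is.finite(dm_col)
  gs_n <- sqrt(sum(gs[ok]^2))
  dm_n <- sqrt(sum(dm_col[ok]^2))
  if (dm_n == 0) stop("zero-norm input: dm")
  if (gs_n == 0) stop("zero-norm input: gs")
  per_echo <- function(beta, d, label) {
    b <- as.numeric(beta$values)[m]
    dv <- as.numeric(d$values)[m]
    d2 <- sum(dv^2)
    if (d2 == 0) stop("zero-norm input: derivative image ", label)
    prod_map <- array(0, dim(beta$values))
    prod_map[m] <- b * dv / d2
    list(term = sum(b * dv) / d2, map = prod_map)
  }
  e1 <- per_echo(beta_e1, d_e1, "e1")
  e2 <- per_echo(beta_e2, d_e2, "e2")
  scale <- gs_n / dm_n
  structure(list(product_e1 = e1$map, product_e2 = e2$map,
                 product_diff = e2$map - e1$map,
                 axis = d_e2$axis, approx_r = scale * (e2$term - e1$term),
                 direct_r = pearson_r(dm_col, gs),
                 scale_factor = scale, term_e1 = e1$term, term_e2 = e2$term),
            class = "map_decomposition")
}

#' Figure and table report for a map decomposition
#'
#' Writes one axial, one sagittal and one coronal slice image per map
#' (beta (*) d / ||d||^2 for each echo and their difference) and a one-row
#' summary table of the inner products and r values.
#'
#' @param decomp A [approx_r()] result.
#' @param slices Integer 3-vector: (axial z, sagittal x, coronal y) slice
#'   indices.
#' @param out_dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Invisibly, the summary data frame (also written as TSV).
#' @export
render_decomposition_report <- function(decomp, slices, out_dir,
                                        prefix = "decomp") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  maps <- list(product_e1 = decomp$product_e1, product_e2 = decomp$product_e2,
               product_diff = decomp$product_diff)
  dims <- dim(decomp$product_e1)
  stopifnot(slices[1] >= 1, slices[1] <= dims[3],
            slices[2] >= 1, slices[2] <= dims[1],
            slices[3] >= 1, slices[3] <= dims[2])
  for (nm in names(maps)) {
    f <- file.path(out_dir, paste0(prefix, "_", decomp$axis, "_", nm, ".png"))
    grDevices::png(f, width = 900, height = 320)
    graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
    graphics::image(maps[[nm]][, , slices[1]], axes = FALSE,
                    main = paste(nm, "axial"))
    graphics::image(maps[[nm]][slices[2], , ], axes = FALSE,
                    main = paste(nm, "sagittal"))
    graphics::image(maps[[nm]][, slices[3], ], axes = FALSE,
                    main = paste(nm, "coronal"))
    grDevices::dev.off()
  }
  summ <- data.frame(axis = decomp$axis, term_e1 = decomp$term_e1,
                     term_e2 = decomp$term_e2,
                     sum_product_diff = sum(decomp$product_diff),
                     scale_factor = decomp$scale_factor,
                     approx_r = decomp$approx_r, direct_r = decomp$direct_r)
  write.table(summ, file.path(out_dir, paste0(prefix, "_", decomp$axis,
                                              "_summary.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(summ)
}
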