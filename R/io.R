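# On-disk interchange: 4-D NIfTI per echo, 6-column whitespace motion
# parameter text (Rx Ry Rz Tx Ty Tz per frame) with a JSON sidecar, and a
# JSON run manifest.

#' Write a synthetic run to disk
#'
#' Each echo as a 4-D NIfTI-1 file, ground-truth motion as 6-column text,
#' the driver as single-column text, and a JSON manifest with TEs, TR,
#' voxel size and seed.
#'
#' @param run A `multi_echo_run`.
#' @param dir Output directory (created).
#' @param prefix Filename prefix.
#' @return Invisibly, the manifest path.
#' @export
write_run <- function(run, dir, prefix = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(run$echoes))
  for (e in seq_along(run$echoes)) {
    paths[e] <- file.path(dir, sprintf("%s_echo%d.nii.gz", prefix, e))
    img <- RNifti::asNifti(run$echoes[[e]])
    RNifti::pixdim(img) <- c(run$voxel_size_mm, run$tr_s)
    RNifti::writeNifti(img, paths[e])
  }
  if (!is.null(run$truth$motion))
    write_motion_params(run$truth$motion,
                        file.path(dir, paste0(prefix, "_truth_motion.1D")))
  if (!is.null(run$truth$gs_driver))
    write.table(run$truth$gs_driver,
                file.path(dir, paste0(prefix, "_driver.1D")),
                row.names = FALSE, col.names = FALSE)
  manifest <- list(echo_files = basename(paths), te_ms = run$te_ms,
                   tr_s = run$tr_s, voxel_size_mm = run$voxel_size_mm,
                   n_volumes = dim(run$echoes[[1]])[4],
                   seed = run$truth$seed, noise_sd = run$truth$noise_sd)
  mpath <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Load a 4-D NIfTI run
#'
#' Reads the volume and discards the first `n_discard` frames (steady-state
#' magnetization).
#'
#' @param path NIfTI file path.
#' @param n_discard Leading frames to drop (default 6).
#' @return List with `data` (4-D array), `voxel_size_mm`, `tr_s`.
#' @export
load_run <- function(path, n_discard = 6L) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- as.array(img)
  stopifnot(length(dim(arr)) == 4)
  if (n_discard > 0) {
    stopifnot(dim(arr)[4] > n_discard)
    arr <- arr[, , , -(seq_len(n_discard)), drop = FALSE]
  }
  list(data = arr, voxel_size_mm = pd[1:3],
       tr_s = if (length(pd) >= 4) pd[4] else NA_real_)
}

#' Write motion parameters as 6-column text
#'
#' One row per frame, order Rx Ry Rz Tx Ty Tz, plus a JSON sidecar
#' recording the sign convention and reference index.
#'
#' @param m `motion_params` object.
#' @param path Output path (sidecar gets `.json` appended).
#' @return Invisibly, `path`.
#' @export
write_motion_params <- function(m, path) {
  write.table(unclass(as.matrix(m)), path, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(columns = axis_names(),
         units = c(rep("deg", 3), rep("mm", 3)),
         sign_convention = attr(m, "sign_convention"),
         reference_index = attr(m, "reference_index")),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read motion parameters written by [write_motion_params()]
#'
#' @param path Path of the 6-column text file.
#' @return A `motion_params` object.
#' @export
read_motion_params <- function(path) {
  vals <- as.matrix(read.table(path))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    motion_params(vals, meta$sign_convention, meta$reference_index)
  } else {
    motion_params(vals)
  }
}
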