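# Build a dense array from sparse voxel values on the bounding grid.
voxels_to_array <- function(truth, values, dim3) {
  arr <- array(0, dim = dim3)
  arr[cbind(truth$i, truth$j, truth$k)] <- values
  arr
}

#' Write a simulated patient visit as NIfTI volumes
#'
#' Exports the digital-reference-object bundle in the field's standard
#' on-disk layout: the 4D DCE series, one 3D VFA volume per flip angle,
#' the 3D B1 ratio map, the 3D ROI mask, a JSON manifest (patient id,
#' group, visit, protocol, seed) and a CSV ground-truth table. Volumes are
#' written with an identity (RAS+) affine; voxels outside the ROI are
#' zero.
#'
#' @param patient A `dro_patient` from [simulate_patient()].
#' @param dir Output directory (created if absent).
#' @return Invisible character vector of the files written.
#' @export
write_patient_nifti <- function(patient, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- patient$truth
  dim3 <- attr(truth, "grid_dim")
  files <- character(0)

  dce_wide <- tidyr::pivot_wider(patient$dce, id_cols = "voxel",
                                 names_from = "frame", values_from = "signal")
  n_frames <- ncol(dce_wide) - 1
  arr4 <- array(0, dim = c(dim3, n_frames))
  idx <- match(dce_wide$voxel, truth$voxel)
  for (f in seq_len(n_frames)) {
    arr4[, , , f][cbind(truth$i[idx], truth$j[idx], truth$k[idx])] <-
      dce_wide[[f + 1]]
  }
  f_dce <- file.path(dir, "dce.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr4), f_dce)
  files <- c(files, f_dce)

  for (ang in sort(unique(patient$vfa$angle))) {
    sub <- patient$vfa[patient$vfa$angle == ang, ]
    vals <- sub$signal[match(truth$voxel, sub$voxel)]
    f <- file.path(dir, sprintf("vfa_fa%02d.nii.gz", round(ang)))
    RNifti::writeNifti(RNifti::asNifti(voxels_to_array(truth, vals, dim3)), f)
    files <- c(files, f)
  }

  b1_vals <- patient$b1$ratio[match(truth$voxel, patient$b1$voxel)]
  f_b1 <- file.path(dir, "b1_ratio.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(voxels_to_array(truth, b1_vals, dim3)), f_b1)
  f_roi <- file.path(dir, "roi_mask.nii.gz")
  RNifti::writeNifti(
    RNifti::asNifti(voxels_to_array(truth, rep(1, nrow(truth)), dim3)), f_roi)
  files <- c(files, f_b1, f_roi)

  f_man <- file.path(dir, "manifest.json")
  jsonlite::write_json(patient$manifest, f_man, auto_unbox = TRUE, pretty = TRUE)
  f_truth <- file.path(dir, "truth.csv")
  utils::write.csv(as.data.frame(truth), f_truth, row.names = FALSE)
  files <- c(files, f_man, f_truth)
  invisible(files)
}

#' Read a DCE NIfTI series back into the long voxel table
#'
#' Inverse of the DCE part of [write_patient_nifti()]: voxels inside the
#' ROI mask become rows of the long `voxel`/`frame`/`time`/`signal` table.
#'
#' @param dir Directory holding `dce.nii.gz`, `roi_mask.nii.gz` and
#'   `manifest.json`.
#' @return Long tibble as produced by [simulate_dce_series()].
#' @export
read_dce_nifti <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  arr <- as.array(RNifti::readNifti(file.path(dir, "dce.nii.gz")))
  roi <- as.array(RNifti::readNifti(file.path(dir, "roi_mask.nii.gz")))
  ijk <- which(roi > 0, arr.ind = TRUE)
  ord <- order(ijk[, 3], ijk[, 2], ijk[, 1])
  ijk <- ijk[ord, , drop = FALSE]
  n_frames <- dim(arr)[4]
  dt <- man$protocol$frame_interval
  sig <- vapply(seq_len(n_frames),
                function(f) arr[, , , f][ijk], numeric(nrow(ijk)))
  tibble::tibble(
    voxel = rep(seq_len(nrow(ijk)), each = n_frames),
    frame = rep(seq_len(n_frames), times = nrow(ijk)),
    time = rep((seq_len(n_frames) - 1) * dt, times = nrow(ijk)),
    signal = as.numeric(t(sig))
  )
}
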