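# NIfTI / JSON / CSV input-output. Volumes go through RNifti; per-study
# metadata (frame times, spacing, truth parameters, seed) lives in a JSON
# sidecar next to the 4D NIfTI.

# plain numeric array from a niftiImage (drop image attributes/pointers)
strip_nifti <- function(img) {
  array(as.numeric(img), dim(img))
}

#' Write a dynamic study to disk
#'
#' Writes the 4D HU volume as NIfTI plus a JSON sidecar with frame times,
#' spacing and (if present) the scalar truth parameters; truth mask volumes
#' are written as an integer-label NIfTI.
#'
#' @param study a [dynamic_study()].
#' @param path output stem; writes `<path>.nii.gz`, `<path>.json` and, with
#'   truth, `<path>_masks.nii.gz` and `<path>_mbf_truth.nii.gz`.
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, path) {
  nii <- paste0(path, ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(study$frames,
                                     pixdim = c(study$spacing_mm, 1)), nii,
                     datatype = "double")
  meta <- list(frame_times_s = study$frame_times_s,
               spacing_mm = study$spacing_mm)
  paths <- c(nii, paste0(path, ".json"))
  if (!is.null(study$truth)) {
    tr <- study$truth
    meta$truth <- list(
      aif = unclass(tr$aif_params),
      shifts = tr$shifts,
      bh_coeffs = tr$bh_coeffs,
      septal_angle_deg = tr$septal_angle_deg,
      heart_center_vox = tr$heart_center_vox,
      aorta_center_vox = tr$aorta_center_vox)
    mnii <- paste0(path, "_masks.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(tr$masks,
                                       pixdim = c(study$spacing_mm, 1)), mnii)
    tnii <- paste0(path, "_mbf_truth.nii.gz")
    mbf <- tr$mbf_map
    mbf[is.na(mbf)] <- -1
    RNifti::writeNifti(RNifti::asNifti(mbf, pixdim = c(study$spacing_mm, 1)),
                       tnii, datatype = "double")
    paths <- c(paths, mnii, tnii)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Read a dynamic study written by [write_study()]
#'
#' @param path the stem passed to [write_study()].
#' @return a [dynamic_study()] (truth masks reattached when present).
#' @export
read_study <- function(path) {
  frames <- strip_nifti(RNifti::readNifti(paste0(path, ".nii.gz")))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  truth <- NULL
  mpath <- paste0(path, "_masks.nii.gz")
  if (!is.null(meta$truth) && file.exists(mpath)) {
    masks <- array(as.integer(round(as.array(RNifti::readNifti(mpath)))),
                   dim(frames)[1:3])
    mbf <- strip_nifti(RNifti::readNifti(paste0(path, "_mbf_truth.nii.gz")))
    mbf[mbf < 0] <- NA_real_
    truth <- list(masks = masks, mbf_map = mbf,
                  aif_params = do.call(aif_params, meta$truth$aif),
                  shifts = meta$truth$shifts,
                  bh_coeffs = meta$truth$bh_coeffs,
                  septal_angle_deg = meta$truth$septal_angle_deg,
                  heart_center_vox = meta$truth$heart_center_vox,
                  aorta_center_vox = meta$truth$aorta_center_vox)
  }
  dynamic_study(frames, meta$frame_times_s, meta$spacing_mm, truth = truth)
}

#' Write / read heart label masks as NIfTI
#' @param masks a [heart_masks()] object.
#' @param path output file (`.nii` / `.nii.gz`).
#' @return invisibly, `path`.
#' @export
write_masks <- function(masks, path) {
  RNifti::writeNifti(RNifti::asNifti(masks$labels,
                                     pixdim = c(masks$spacing_mm, 1)), path)
  invisible(path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path) {
  img <- RNifti::readNifti(path)
  labels <- array(as.integer(round(as.array(img))), dim(img))
  heart_masks(labels, attr(img, "pixdim")[1:3] %||% c(1, 1, 1))
}

#' Write / read a cohort table as CSV
#' @param table a `cohort_table` data.frame.
#' @param path CSV file.
#' @return invisibly `path`; `read_cohort` returns the table.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tb) <- c("cohort_table", "data.frame")
  tb
}

#' Write a perfusion map as NIfTI
#'
#' MBF in mL·min^-1·(100 g)^-1; voxels outside the myocardium are NaN. The
#' per-cluster fit table, when present, goes to a CSV next to the volume.
#'
#' @param map a `perfusion_map`.
#' @param path output NIfTI file.
#' @return invisibly, the paths written.
#' @export
write_perfusion_map <- function(map, path) {
  RNifti::writeNifti(RNifti::asNifti(map$mbf), path)
  paths <- path
  if (!is.null(map$clusters)) {
    cpath <- sub("\\.nii(\\.gz)?$", "_clusters.csv", path)
    utils::write.csv(map$clusters, cpath, row.names = FALSE)
    paths <- c(paths, cpath)
  }
  invisible(paths)
}

#' Write an AHA report and polar raster as CSV, territories as JSON
#' @param report an [aha16_report()] result (optionally with relative MBF).
#' @param path CSV file.
#' @return invisibly `path`.
#' @export
write_aha_report <- function(report, path) {
  df <- as.data.frame(report)
  df$global_mean_mbf <- attr(report, "global_mean_mbf")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aha_report
#' @param polar a `polar_map`.
#' @export
write_polar_csv <- function(polar, path) {
  utils::write.csv(polar$raster, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aha_report
#' @param territories named list of [territory_mbf()] results.
#' @param threshold ischemia threshold recorded alongside.
#' @export
write_territories_json <- function(territories, path, threshold = 200) {
  obj <- lapply(names(territories), function(v) {
    t <- territories[[v]]
    list(vessel = v, representative_mbf = t$value,
         pair = t$pair, evaluable = t$evaluable,
         ischemic = if (t$evaluable) unname(t$value < threshold) else NA)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
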