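## File interfaces: NIfTI images with JSON sidecars, time-activity and dose
## CSVs.

#' Write / read a voxel image as NIfTI with a JSON sidecar
#'
#' The image is stored as `.nii.gz` with the voxel spacing (mm) in the
#' header; the sidecar (`<path with .json extension>`) records the role,
#' acquisition time and optional acquisition metadata.
#'
#' @param image A [voxel_image()].
#' @param path Destination path ending in `.nii` or `.nii.gz`.
#' @param cf_cps_per_MBq Optional calibration factor to record.
#' @param seed Optional generator seed to record.
#' @return `read_voxel_image()` returns a [voxel_image()];
#'   `write_voxel_image()` the path, invisibly.
#' @export
write_voxel_image <- function(image, path, cf_cps_per_MBq = NULL,
                              seed = NULL) {
  stopifnot(inherits(image, "voxel_image"))
  nii <- RNifti::asNifti(image$data)
  RNifti::pixdim(nii) <- image$spacing_mm
  RNifti::writeNifti(nii, path)
  side <- list(role = image$role, time_h = image$time_h,
               calibration_factor_cps_per_MBq = cf_cps_per_MBq,
               seed = seed)
  jsonlite::write_json(side[!vapply(side, is.null, logical(1))],
                       sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' @rdname write_voxel_image
#' @export
read_voxel_image <- function(path) {
  nii <- RNifti::readNifti(path)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  voxel_image(array(as.numeric(nii), dim(nii)),
              spacing_mm = RNifti::pixdim(nii)[1:3],
              role = side$role, time_h = side$time_h %||% NA_real_)
}

#' Write / read a time-activity series as CSV
#'
#' Columns organ, time_h, activity_MBq, volume_ml, mass_g; the organ label
#' and administered activity travel in the file so a series round-trips.
#'
#' @param series A [time_activity_series()].
#' @param path File path.
#' @return `read_time_activity_csv()` a [time_activity_series()];
#'   the writer returns the path, invisibly.
#' @export
write_time_activity_csv <- function(series, path) {
  stopifnot(inherits(series, "time_activity_series"))
  df <- cbind(organ = attr(series, "organ"),
              as.data.frame(series),
              admin_MBq = attr(series, "admin_MBq"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_time_activity_csv
#' @export
read_time_activity_csv <- function(path) {
  df <- utils::read.csv(path)
  time_activity_series(df[c("time_h", "activity_MBq", "volume_ml", "mass_g")],
                       organ = df$organ[1], admin_MBq = df$admin_MBq[1])
}
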