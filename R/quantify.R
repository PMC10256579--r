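## Image quantification: counts -> activity conversion, fixed-threshold VOI
## segmentation, and per-organ time-activity extraction by voxel summation.

#' Convert a count-rate image to an activity image
#'
#' Divides every voxel by the system-volume calibration factor. Geometry and
#' acquisition time are unchanged; the role tag becomes `"activity"`.
#'
#' @param image A [voxel_image()] with role `"counts"`.
#' @param cf A [calibration_factor()] (or a positive scalar, cps/MBq).
#' @return A [voxel_image()] with role `"activity"`.
#' @export
counts_to_activity <- function(image, cf) {
  stopifnot(inherits(image, "voxel_image"))
  if (image$role != "counts")
    stop(sprintf("expected a counts image, got role '%s'", image$role))
  v <- if (inherits(cf, "calibration_factor")) cf$value else cf
  if (!is.numeric(v) || length(v) != 1L || v <= 0)
    stop("calibration factor must be a single positive number")
  voxel_image(image$data / v, image$spacing_mm, role = "activity",
              time_h = image$time_h)
}

#' Fixed-threshold VOI segmentation
#'
#' Thresholds at `fraction` of the maximum voxel value inside a search
#' region (the study used a fixed 35% threshold on SPECT where anatomical
#' imaging was unavailable), then keeps the largest 6-connected component;
#' ties on component size are broken by total intensity. Thresholding within
#' a local search region rather than the whole image mirrors per-organ
#' segmentation practice.
#'
#' @param image A [voxel_image()].
#' @param region Logical array (same grid) delimiting the search region.
#' @param fraction Threshold fraction of the region maximum, in (0, 1);
#'   default 0.35.
#' @return A logical mask array (same grid).
#' @export
segment_threshold <- function(image, region, fraction = 0.35) {
  stopifnot(inherits(image, "voxel_image"))
  if (!(fraction > 0 && fraction < 1)) stop("fraction must lie in (0, 1)")
  if (!is.logical(region) || !identical(dim(region), dim(image$data)))
    stop("region must be a logical array on the image grid")
  if (!any(region)) stop("search region is empty")
  mx <- max(image$data[region])
  if (mx <= 0) stop("nothing to segment: search region maximum is 0")
  cand <- region & (image$data >= fraction * mx)
  lab <- label_components6(cand)
  ncomp <- max(lab)
  if (ncomp <= 1L) return(cand)
  sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    totals <- vapply(best, function(l) sum(image$data[lab == l]), numeric(1))
    best <- best[which.max(totals)]
  }
  lab == best
}

#' Time-activity series container
#'
#' @param samples Data frame with columns `time_h`, `activity_MBq`,
#'   `volume_ml`, `mass_g`; times strictly increasing, activities >= 0.
#' @param organ Organ label.
#' @param admin_MBq Administered activity A0 (> 0), used to normalise TIA to
#'   a TIAC.
#' @return Object of class `time_activity_series`.
#' @export
time_activity_series <- function(samples, organ = NA_character_,
                                 admin_MBq = NA_real_) {
  req <- c("time_h", "activity_MBq", "volume_ml", "mass_g")
  if (!all(req %in% names(samples)))
    stop("samples needs columns time_h, activity_MBq, volume_ml, mass_g")
  if (nrow(samples) > 1 && any(diff(samples$time_h) <= 0))
    stop("times must be strictly increasing")
  if (any(samples$activity_MBq < 0)) stop("activities must be >= 0")
  if (!is.na(admin_MBq) && admin_MBq <= 0)
    stop("administered activity must be > 0")
  structure(samples[req],
            organ = organ, admin_MBq = admin_MBq,
            class = c("time_activity_series", "data.frame"))
}

#' @export
print.time_activity_series <- function(x, ...) {
  cat(sprintf("<time_activity_series> organ '%s', %d time-point(s)",
              attr(x, "organ"), nrow(x)))
  if (!is.na(attr(x, "admin_MBq")))
    cat(sprintf(", A0 = %g MBq", attr(x, "admin_MBq")))
  cat("\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Extract a per-organ time-activity series by voxel summation
#'
#' For each activity image: VOI activity is the sum of voxel values inside
#' the mask (recovery-corrected at the VOI volume if a curve is supplied),
#' VOI volume is voxel count times voxel volume, and VOI mass integrates the
#' density map over the mask (uniform 1.0 g/mL when none is given).
#'
#' @param images List of [voxel_image()]s with role `"activity"`, one per
#'   time-point, all on the mask's grid.
#' @param mask Logical VOI mask array.
#' @param organ Organ label for the series.
#' @param density Optional density [voxel_image()] on the same grid.
#' @param admin_MBq Administered activity A0.
#' @param recovery Optional [compute_recovery_curve()] result; when given,
#'   each VOI activity is divided by RC(VOI volume).
#' @return A [time_activity_series()].
#' @export
extract_time_activity <- function(images, mask, organ = NA_character_,
                                  density = NULL, admin_MBq = NA_real_,
                                  recovery = NULL) {
  if (length(images) < 1L) stop("at least one image is required")
  if (!is.logical(mask)) stop("mask must be a logical array")
  if (!any(mask)) stop("mask is empty")
  for (i in seq_along(images)) {
    img <- images[[i]]
    stopifnot(inherits(img, "voxel_image"))
    if (img$role != "activity")
      stop(sprintf("image %d has role '%s', expected 'activity'", i, img$role))
    if (!identical(dim(img$data), dim(mask)))
      stop(sprintf("image %d is not on the mask's grid", i))
  }
  if (!is.null(density) && !identical(dim(density$data), dim(mask)))
    stop("density image is not on the mask's grid")
  voxvol <- voxel_volume_ml(images[[1]])
  vol <- sum(mask) * voxvol
  mass <- if (is.null(density)) vol * 1.0 else sum(density$data[mask]) * voxvol
  act <- vapply(images, function(img) sum(img$data[mask]), numeric(1))
  if (!is.null(recovery)) act <- apply_recovery_correction(act, vol, recovery)
  times <- vapply(images, function(img) img$time_h, numeric(1))
  time_activity_series(
    data.frame(time_h = times, activity_MBq = act, volume_ml = vol,
               mass_g = mass),
    organ = organ, admin_MBq = admin_MBq)
}
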