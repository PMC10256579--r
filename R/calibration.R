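## Imaging-system characterisation: system-volume calibration factor
## (counts -> activity) and recovery coefficients (partial-volume
## correction), as determined at site set-up in a standardised quantitative
## imaging network.

#' Calibration factor container
#'
#' @param value System sensitivity, counts per second per MBq; must be > 0.
#' @param system Optional imaging-system identifier.
#' @param reference_date Optional reference date string.
#' @return Object of class `calibration_factor`.
#' @export
calibration_factor <- function(value, system = NA_character_,
                               reference_date = NA_character_) {
  if (!is.numeric(value) || length(value) != 1L || value <= 0)
    stop("calibration factor must be a single positive number")
  structure(list(value = as.numeric(value), system = system,
                 reference_date = reference_date),
            class = "calibration_factor")
}

#' @export
print.calibration_factor <- function(x, ...) {
  cat(sprintf("<calibration_factor> %g cps/MBq", x$value))
  if (!is.na(x$system)) cat(sprintf(" [%s]", x$system))
  cat("\n")
  invisible(x)
}

#' Determine the system-volume calibration factor
#'
#' Sensitivity of the imaging system from an acquisition of a known activity
#' in a known volume: count rate divided by the activity present at
#' acquisition time (the caller decay-corrects the certificate activity).
#'
#' @param total_count_rate_cps Total count rate over the phantom (> 0).
#' @param true_activity_MBq Activity at acquisition time (> 0).
#' @inheritParams calibration_factor
#' @return A [calibration_factor()].
#' @examples
#' compute_calibration_factor(6e5, 120) # 5000 cps/MBq
#' @export
compute_calibration_factor <- function(total_count_rate_cps,
                                       true_activity_MBq,
                                       system = NA_character_,
                                       reference_date = NA_character_) {
  if (total_count_rate_cps <= 0 || true_activity_MBq <= 0)
    stop("count rate and activity must both be > 0")
  calibration_factor(total_count_rate_cps / true_activity_MBq,
                     system = system, reference_date = reference_date)
}

#' Recovery curve from a sphere series
#'
#' Recovery coefficients RC = measured/true per sphere, clipped to at most 1
#' (noise can push a ratio above unity; physics cannot), sorted by volume,
#' and repaired to be non-decreasing with volume by least-squares
#' pool-adjacent-violators isotonic regression — partial-volume loss can
#' only worsen as objects shrink.
#'
#' @param spheres Data frame with columns `volume_ml`, `measured_MBq`,
#'   `true_MBq` (at least 2 spheres, distinct volumes, positive activities).
#' @return Object of class `recovery_curve`: data frame of nodes
#'   (`volume_ml`, `rc`).
#' @examples
#' compute_recovery_curve(data.frame(volume_ml = c(1, 10, 100),
#'                                   measured_MBq = c(3, 7, 9.5),
#'                                   true_MBq = 10))
#' @export
compute_recovery_curve <- function(spheres) {
  req <- c("volume_ml", "measured_MBq", "true_MBq")
  if (!all(req %in% names(spheres)))
    stop("spheres needs columns volume_ml, measured_MBq, true_MBq")
  if (nrow(spheres) < 2L) stop("at least 2 spheres are required")
  if (anyDuplicated(spheres$volume_ml)) stop("duplicate sphere volumes")
  if (any(spheres$true_MBq <= 0)) stop("true activities must be > 0")
  if (any(spheres$measured_MBq <= 0))
    stop("measured activities must be > 0 to define a recovery coefficient")
  ord <- order(spheres$volume_ml)
  vol <- spheres$volume_ml[ord]
  rc <- pmin(spheres$measured_MBq[ord] / spheres$true_MBq[ord], 1)
  rc <- pmin(stats::isoreg(seq_along(rc), rc)$yf, 1)
  structure(data.frame(volume_ml = vol, rc = rc), class = c("recovery_curve",
                                                            "data.frame"))
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("<recovery_curve> %d nodes, RC %s over %s mL\n", nrow(x),
              paste(format(range(x$rc), digits = 3), collapse = "-"),
              paste(format(range(x$volume_ml)), collapse = "-")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Interpolate a recovery coefficient at a volume
#'
#' Linear interpolation in log10(volume) between nodes (the conventional
#' axis for recovery curves); volumes outside the node range take the
#' nearest node's RC. The result is continuous and non-decreasing over the
#' whole positive-volume domain.
#'
#' @param curve A [compute_recovery_curve()] result.
#' @param volume_ml Volume(s) at which to evaluate, > 0.
#' @return Recovery coefficient(s) in (0, 1].
#' @export
recovery_at <- function(curve, volume_ml) {
  if (!inherits(curve, "recovery_curve") || nrow(curve) == 0L)
    stop("a non-empty recovery_curve is required")
  if (any(volume_ml <= 0)) stop("volume must be > 0")
  stats::approx(log10(curve$volume_ml), curve$rc, xout = log10(volume_ml),
                rule = 2)$y
}

#' Correct a measured activity for partial-volume loss
#'
#' Divides the measured VOI activity by the recovery coefficient
#' interpolated at the VOI volume. Since RC <= 1 the correction never
#' decreases activity.
#'
#' @param measured_MBq Measured activity.
#' @param volume_ml VOI volume (> 0).
#' @param curve A [compute_recovery_curve()] result.
#' @return Corrected activity, MBq.
#' @examples
#' rc <- compute_recovery_curve(data.frame(volume_ml = c(1, 10),
#'                                         measured_MBq = c(3, 7),
#'                                         true_MBq = 10))
#' apply_recovery_correction(7, 10, rc) # 10
#' @export
apply_recovery_correction <- function(measured_MBq, volume_ml, curve) {
  measured_MBq / recovery_at(curve, volume_ml)
}

#' Serialise / deserialise calibration objects as JSON
#'
#' @param x A [calibration_factor()] or [compute_recovery_curve()] result.
#' @param path File path.
#' @return `read_*` return the reconstructed object; `write_*` the path,
#'   invisibly.
#' @export
write_calibration_factor <- function(x, path) {
  stopifnot(inherits(x, "calibration_factor"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_calibration_factor
#' @export
read_calibration_factor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_factor(obj$value, obj$system %||% NA_character_,
                     obj$reference_date %||% NA_character_)
}

#' @rdname write_calibration_factor
#' @export
write_recovery_curve <- function(x, path) {
  stopifnot(inherits(x, "recovery_curve"))
  jsonlite::write_json(list(volume_ml = x$volume_ml, rc = x$rc), path,
                       digits = NA)
  invisible(path)
}

#' @rdname write_calibration_factor
#' @export
read_recovery_curve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(data.frame(volume_ml = obj$volume_ml, rc = obj$rc),
            class = c("recovery_curve", "data.frame"))
}
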