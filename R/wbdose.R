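## Whole-body MIRD dosimetry from retention measurements, using a
## mass-adjusted whole-body self-irradiation S-factor. The whole-body
## absorbed dose is frequently used as a surrogate for the absorbed dose to
## the bone marrow.

#' Patient metadata
#'
#' @param id Patient identifier.
#' @param mass_kg Body mass (> 0).
#' @param admin_MBq Administered activity A0 (> 0).
#' @param stimulation `"rhTSH"` or `"THW"`.
#' @param centre Recruiting centre identifier.
#' @param activity_group Nominal administered activity group, GBq (1.1, 2.5
#'   or 3.7).
#' @return Object of class `ridose_patient` (a one-row data frame).
#' @export
patient <- function(id, mass_kg, admin_MBq,
                    stimulation = c("rhTSH", "THW"), centre = NA,
                    activity_group = NA_real_) {
  stimulation <- match.arg(stimulation)
  if (mass_kg <= 0) stop("patient mass must be > 0")
  if (admin_MBq <= 0) stop("administered activity must be > 0")
  structure(data.frame(patient_id = id, mass_kg = mass_kg,
                       admin_MBq = admin_MBq, stimulation = stimulation,
                       centre = centre, activity_group = activity_group,
                       stringsAsFactors = FALSE),
            class = c("ridose_patient", "data.frame"))
}

#' Mass-adjusted whole-body S-factor
#'
#' Whole-body self-irradiation S-factor scaled to the patient's mass:
#' `S = 1.34e-4 * m_p^-0.921` Gy/(MBq h), with `m_p` in kg. Strictly
#' decreasing in mass; at 1 kg the S-factor equals the coefficient itself.
#'
#' @param mass_kg Patient mass in kg (> 0).
#' @return S-factor in Gy MBq^-1 h^-1.
#' @examples
#' wb_s_factor(70) # 2.678e-6
#' @export
wb_s_factor <- function(mass_kg) {
  if (any(mass_kg <= 0)) stop("patient mass must be > 0")
  1.34e-4 * mass_kg^(-0.921)
}

#' Whole-body absorbed dose from a retention fit
#'
#' MIRD formalism with the mass-adjusted S-factor:
#' `D = TIA * S(m_p)`, reported together with the dose per unit
#' administered activity `d = D / A0 * 1000` mGy/MBq.
#'
#' @param fit A `kinetic_fit` of the whole-body retention (TIA in MBq h),
#'   see [fit_retention()].
#' @param pat A [patient()].
#' @return A [dose_record()] row with organ `"whole-body"`.
#' @export
wb_dose <- function(fit, pat) {
  stopifnot(inherits(fit, "kinetic_fit"), inherits(pat, "ridose_patient"))
  if (is.na(pat$mass_kg)) stop("patient mass is required")
  d <- fit$tia_MBq_h * wb_s_factor(pat$mass_kg)
  dose_record(pat$patient_id, pat$centre, "whole-body", d, pat$admin_MBq,
              method = "whole-body",
              flags = paste(fit$flags, collapse = ";"))
}
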