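## End-to-end conveniences: a study-like default phantom and a seeded
## synthetic cohort exercising the whole-body pathway.

#' A study-like default phantom specification
#'
#' Six normal organs with field-realistic geometry, uptake and effective
#' half-lives (neck remnant near 68 h, salivary glands near 9 h, lungs at
#' reduced density), suitable for end-to-end pipeline validation against
#' the generator's analytic ground truth.
#'
#' @param fov Field-of-view preset passed to [phantom_spec()].
#' @param conc_scale Multiplies every organ's activity concentration
#'   (doses scale linearly with it, emulating a change of administered
#'   activity).
#' @return A [phantom_spec()].
#' @export
example_phantom_spec <- function(fov = "full", conc_scale = 1) {
  organs <- list(
    phantom_organ("neck uptake", "sphere", c(48, 48, 150), 12,
                  0.20 * conc_scale, 68),
    phantom_organ("salivary glands", "ellipsoid", c(48, 48, 178),
                  c(20, 14, 10), 0.10 * conc_scale, 9.3),
    phantom_organ("left lung", "ellipsoid", c(26, 48, 96), c(16, 20, 32),
                  0.012 * conc_scale, 14, density_g_per_ml = 0.3),
    phantom_organ("right lung", "ellipsoid", c(70, 48, 96), c(16, 20, 32),
                  0.012 * conc_scale, 14, density_g_per_ml = 0.3),
    phantom_organ("liver", "ellipsoid", c(34, 48, 44), c(26, 22, 22),
                  0.015 * conc_scale, 16, density_g_per_ml = 1.05),
    phantom_organ("spleen", "ellipsoid", c(74, 48, 40), c(12, 12, 16),
                  0.018 * conc_scale, 14, density_g_per_ml = 1.05))
  phantom_spec(shape = c(24, 24, 48), spacing_mm = 4, organs = organs,
               fov = fov)
}

#' Simulate a multi-centre whole-body dosimetry cohort
#'
#' Generates a cohort of patients with bi-exponential whole-body retention
#' (fast renal clearance plus a slower retained component), centre-specific
#' external-counting schedules (centres 1-2 measure out to 167 h, centres
#' 3-4 stop near 44 h, matching hospital-stay practice), 1.1/3.7 GBq
#' activity groups and rhTSH/THW stimulation, runs the retention fit and
#' MIRD whole-body dose for each patient, and returns the dose records
#' joined to the patients together with the generator's true TIACs.
#'
#' @param n Number of patients.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param rel_noise Relative measurement noise on retention values.
#' @return List: `cohort` (a [cohort_table()]), `patients`, `doses`,
#'   `truth` (data frame patient_id, true_tiac_h, fitted_tiac_h).
#' @export
simulate_cohort <- function(n = 20, seed = 1L, rel_noise = 0.05) {
  schedules <- list(`1` = c(2, 6, 24, 48, 96, 167),
                    `2` = c(2, 6, 24, 48, 120, 165),
                    `3` = c(2, 6, 24, 42), `4` = c(2, 6, 24, 44))
  draw <- with_seed(seed, {
    centre <- sample(1:4, n, replace = TRUE)
    data.frame(
      centre = centre,
      mass_kg = round(stats::rnorm(n, 75, 12), 1),
      ## centre 4 mixes 1.1 and 3.7 GBq; others administer 3.7 GBq
      activity_group = ifelse(centre == 4 & stats::runif(n) < 0.5, 1.1, 3.7),
      ## THW used at centres 1-2 only, for a minority of patients
      stim = ifelse(centre <= 2 & stats::runif(n) < 0.3, "THW", "rhTSH"),
      f_fast = stats::runif(n, 0.4, 0.7),
      t_fast = stats::runif(n, 4, 10),
      t_slow = stats::runif(n, 18, 30))
  })
  draw$mass_kg <- pmax(draw$mass_kg, 40)
  doses <- patients <- truth <- vector("list", n)
  for (i in seq_len(n)) {
    admin <- draw$activity_group[i] * 1000
    rs <- make_retention_series(retention_spec(
      fractions = c(draw$f_fast[i], 1 - draw$f_fast[i]),
      half_lives_h = c(draw$t_fast[i], draw$t_slow[i]),
      times_h = schedules[[as.character(draw$centre[i])]],
      rel_noise = rel_noise,
      seed = as.integer((as.numeric(seed) * 7919 + i) %% 2147483647),
      mass_kg = draw$mass_kg[i], admin_MBq = admin,
      stimulation = draw$stim[i]))
    fit <- fit_retention(rs)
    pat <- patient(sprintf("P%03d", i), draw$mass_kg[i], admin,
                   stimulation = draw$stim[i], centre = draw$centre[i],
                   activity_group = draw$activity_group[i])
    doses[[i]] <- wb_dose(fit, pat)
    patients[[i]] <- pat
    truth[[i]] <- data.frame(patient_id = pat$patient_id,
                             true_tiac_h = rs$true_tiac_h,
                             fitted_tiac_h = fit$tiac_h)
  }
  doses <- do.call(rbind, doses)
  patients <- do.call(rbind, lapply(patients, as.data.frame))
  list(cohort = cohort_table(doses, patients), patients = patients,
       doses = doses, truth = do.call(rbind, truth))
}
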