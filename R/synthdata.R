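## Digital phantom and acquisition simulation.
##
## The generator emulates the study conditions the pipeline was designed for:
## organs with mono-exponential washout sampled on a voxel grid, SPECT-like
## acquisitions (system sensitivity, Gaussian partial-volume blur, Poisson
## counting noise, centre-specific schedules and FOV restrictions),
## bi-exponential whole-body retention, and calibration/sphere series.
## Every generated dataset carries machine-readable ground truth so
## downstream tests never re-derive truth by hand.

## Organs the study's dosimetry vocabulary covers; the abdominal subset is
## outside a head/neck-only field of view.
.organ_vocabulary <- c("neck uptake", "left lung", "right lung",
                       "salivary glands", "bones", "liver", "left kidney",
                       "right kidney", "spleen", "urinary bladder", "L2-L4")
.abdominal_organs <- c("liver", "left kidney", "right kidney", "spleen",
                       "urinary bladder", "L2-L4")

#' Describe one phantom organ
#'
#' @param name Organ label (free text; the study vocabulary is neck uptake,
#'   left/right lung, salivary glands, bones, liver, left/right kidney,
#'   spleen, urinary bladder, L2-L4).
#' @param type Geometric primitive: `"sphere"`, `"ellipsoid"` or `"box"`.
#' @param centre_mm Centre in mm (grid coordinates start at 0 at the first
#'   voxel face; a voxel's centre sits at `(index - 0.5) * spacing`).
#' @param radii_mm Radius (sphere) or per-axis half-extents (ellipsoid, box).
#' @param conc_MBq_per_ml Activity concentration at t = 0.
#' @param t_eff_h Effective half-life, hours; must not exceed
#'   [i131_half_life_h()].
#' @param density_g_per_ml Organ density (default soft tissue, 1.0).
#' @return A list describing the organ, for [phantom_spec()].
#' @export
phantom_organ <- function(name, type = c("sphere", "ellipsoid", "box"),
                          centre_mm, radii_mm, conc_MBq_per_ml, t_eff_h,
                          density_g_per_ml = 1.0) {
  type <- match.arg(type)
  if (type == "sphere" && length(radii_mm) == 1L) radii_mm <- rep(radii_mm, 3L)
  if (length(centre_mm) != 3L || length(radii_mm) != 3L)
    stop("centre_mm and radii_mm must have length 3 (or scalar radius for a sphere)")
  if (any(radii_mm <= 0)) stop(sprintf("organ '%s': radii must be > 0", name))
  if (conc_MBq_per_ml < 0) stop(sprintf("organ '%s': concentration must be >= 0", name))
  if (t_eff_h <= 0 || t_eff_h > i131_half_life_h())
    stop(sprintf("organ '%s': effective half-life must lie in (0, %g] h",
                 name, i131_half_life_h()))
  if (density_g_per_ml <= 0) stop(sprintf("organ '%s': density must be > 0", name))
  list(name = name, type = type, centre_mm = as.numeric(centre_mm),
       radii_mm = as.numeric(radii_mm), conc_MBq_per_ml = conc_MBq_per_ml,
       t_eff_h = t_eff_h, density_g_per_ml = density_g_per_ml)
}

#' Specify a digital phantom
#'
#' @param shape Grid shape, voxels per axis (length 3).
#' @param spacing_mm Voxel spacing, mm (scalar or length 3).
#' @param organs List of [phantom_organ()] descriptions. Primitives may not
#'   overlap and must lie inside the grid.
#' @param background_density_g_per_ml Density outside all organs.
#' @param fov Field-of-view preset: `"full"` keeps every organ;
#'   `"head-neck-only"` drops the abdominal organs (liver, kidneys, spleen,
#'   urinary bladder, L2-L4), emulating a single head/neck acquisition.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing_mm, organs,
                         background_density_g_per_ml = 1.0,
                         fov = c("full", "head-neck-only")) {
  fov <- match.arg(fov)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be 3 positive integers")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (any(spacing_mm <= 0)) stop("spacing must be > 0")
  if (background_density_g_per_ml <= 0) stop("background density must be > 0")
  extent <- shape * spacing_mm
  for (org in organs) {
    lo <- org$centre_mm - org$radii_mm
    hi <- org$centre_mm + org$radii_mm
    if (any(lo < 0) || any(hi > extent))
      stop(sprintf("organ '%s' lies outside the grid", org$name))
  }
  structure(list(shape = shape, spacing_mm = as.numeric(spacing_mm),
                 organs = organs,
                 background_density_g_per_ml = background_density_g_per_ml,
                 fov = fov),
            class = "phantom_spec")
}

## logical inside-mask of one primitive on the grid (voxel-centre rule)
.primitive_mask <- function(org, shape, spacing_mm) {
  xs <- (seq_len(shape[1]) - 0.5) * spacing_mm[1]
  ys <- (seq_len(shape[2]) - 0.5) * spacing_mm[2]
  zs <- (seq_len(shape[3]) - 0.5) * spacing_mm[3]
  if (org$type == "box") {
    ix <- abs(xs - org$centre_mm[1]) <= org$radii_mm[1]
    iy <- abs(ys - org$centre_mm[2]) <= org$radii_mm[2]
    iz <- abs(zs - org$centre_mm[3]) <= org$radii_mm[3]
    return(outer(outer(ix, iy, `&`), iz, `&`))
  }
  ax <- ((xs - org$centre_mm[1]) / org$radii_mm[1])^2
  ay <- ((ys - org$centre_mm[2]) / org$radii_mm[2])^2
  az <- ((zs - org$centre_mm[3]) / org$radii_mm[3])^2
  outer(outer(ax, ay, `+`), az, `+`) <= 1
}

#' Rasterise a phantom: density image, VOI masks and ground truth
#'
#' Voxelises each organ primitive (a voxel belongs to a primitive when its
#' centre is inside), paints the density image and tabulates the ground
#' truth every downstream test checks against: voxelized volume and mass,
#' true activity at t = 0 (concentration x voxelized volume), effective
#' half-life, the analytic time-integrated activity, and the organ dose
#' under the charged-particle local-deposition model.
#'
#' @param spec A [phantom_spec()].
#' @param delta Kernel energy constant used for the ground-truth dose column
#'   (default [energy_delta()]).
#' @return A list with `density` ([voxel_image()]), `masks` (named list of
#'   logical arrays), `truth` (data frame: organ, conc_MBq_per_ml,
#'   volume_ml, mass_g, activity_MBq, t_eff_h, tia_MBq_h, dose_Gy) and the
#'   `spec`.
#' @export
make_phantom <- function(spec, delta = energy_delta()) {
  stopifnot(inherits(spec, "phantom_spec"))
  organs <- spec$organs
  if (spec$fov == "head-neck-only")
    organs <- Filter(function(o) !(o$name %in% .abdominal_organs), organs)
  voxvol <- voxel_volume_ml(spec$spacing_mm)
  dens <- array(spec$background_density_g_per_ml, spec$shape)
  masks <- list()
  occupancy <- array(FALSE, spec$shape)
  rows <- list()
  for (org in organs) {
    m <- .primitive_mask(org, spec$shape, spec$spacing_mm)
    if (any(m & occupancy))
      stop(sprintf("organ '%s' overlaps a previously placed organ", org$name))
    occupancy <- occupancy | m
    dens[m] <- org$density_g_per_ml
    masks[[org$name]] <- m
    vol <- sum(m) * voxvol
    act <- org$conc_MBq_per_ml * vol
    mass <- vol * org$density_g_per_ml
    tia <- act * org$t_eff_h / log(2)
    rows[[org$name]] <- data.frame(
      organ = org$name, conc_MBq_per_ml = org$conc_MBq_per_ml,
      volume_ml = vol, mass_g = mass, activity_MBq = act,
      t_eff_h = org$t_eff_h, tia_MBq_h = tia,
      dose_Gy = if (mass > 0) tia * delta / mass else 0,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(density = voxel_image(dens, spec$spacing_mm, role = "density"),
       masks = masks, truth = truth, spec = spec)
}

#' Specify a simulated SPECT acquisition series
#'
#' The study schedule allowed an enrolment scan between 24 and 96 h and
#' optional scans from 6 to 168 h post administration; the simulator accepts
#' any strictly increasing schedule within a generous 0-360 h window.
#'
#' @param times_h Imaging time-points, hours post administration, strictly
#'   increasing, each within \[0, 360\].
#' @param cf_cps_per_MBq System sensitivity applied to turn activity into
#'   count rate.
#' @param sigma_mm Isotropic Gaussian blur emulating system resolution /
#'   partial-volume loss; 0 disables.
#' @param noise `"none"` or `"poisson"` (counting noise on the count-rate
#'   map).
#' @param seed Integer seed; identical seeds reproduce identical images.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(times_h, cf_cps_per_MBq = 1,
                             sigma_mm = 0, noise = c("none", "poisson"),
                             seed = 1L) {
  noise <- match.arg(noise)
  if (length(times_h) < 1L) stop("at least one time-point is required")
  if (any(diff(times_h) <= 0)) stop("time-points must be strictly increasing")
  if (any(times_h < 0 | times_h > 360))
    stop("time-points must lie within [0, 360] h post administration")
  if (cf_cps_per_MBq <= 0) stop("calibration factor must be > 0")
  if (sigma_mm < 0) stop("sigma must be >= 0")
  structure(list(times_h = as.numeric(times_h),
                 cf_cps_per_MBq = cf_cps_per_MBq, sigma_mm = sigma_mm,
                 noise = noise, seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' Simulate a time series of count-rate images from a phantom
#'
#' At each time-point the organ activity map decays as
#' `conc * 2^(-t / t_eff)`, is blurred by the acquisition's Gaussian
#' resolution model (normalised kernel: total activity on the grid is
#' conserved for objects clear of the edge), scaled by the system
#' sensitivity, and optionally degraded by Poisson counting noise.
#'
#' @param phantom Output of [make_phantom()].
#' @param acq An [acquisition_spec()].
#' @return List of count-rate [voxel_image()]s, one per time-point, with a
#'   `cf_cps_per_MBq` attribute recording the sensitivity applied.
#' @export
make_timeseries <- function(phantom, acq) {
  stopifnot(inherits(acq, "acquisition_spec"))
  spec <- phantom$spec
  organs <- Filter(function(o) o$name %in% names(phantom$masks), spec$organs)
  voxvol <- voxel_volume_ml(spec$spacing_mm)
  out <- vector("list", length(acq$times_h))
  for (i in seq_along(acq$times_h)) {
    t <- acq$times_h[i]
    act <- array(0, spec$shape) # per-voxel activity, MBq
    for (org in organs)
      act[phantom$masks[[org$name]]] <-
        org$conc_MBq_per_ml * voxvol * 2^(-t / org$t_eff_h)
    if (acq$sigma_mm > 0)
      act <- gaussian_blur3(act, acq$sigma_mm, spec$spacing_mm)
    counts <- act * acq$cf_cps_per_MBq
    if (acq$noise == "poisson")
      counts <- with_seed(acq$seed + i,
                          array(rpois(length(counts), lambda = counts),
                                dim(counts)))
    out[[i]] <- voxel_image(counts, spec$spacing_mm, role = "counts",
                            time_h = t)
  }
  attr(out, "cf_cps_per_MBq") <- acq$cf_cps_per_MBq
  out
}

#' Specify a whole-body retention model
#'
#' A 1- or 2-exponential retention model normalised to 1 at administration,
#' as assumed by the whole-body dose fit, together with the external-counting
#' schedule and the patient metadata the MIRD calculation needs.
#'
#' @param fractions Component fractions at t = 0; positive, summing to 1.
#' @param half_lives_h Effective half-lives per component, each in
#'   (0, [i131_half_life_h()]\].
#' @param times_h Measurement times, hours post administration.
#' @param rel_noise Relative (multiplicative Gaussian) measurement noise.
#' @param seed Integer seed for the noise.
#' @param mass_kg Patient mass.
#' @param admin_MBq Administered activity A0.
#' @param stimulation `"rhTSH"` or `"THW"`.
#' @return An object of class `retention_spec`.
#' @export
retention_spec <- function(fractions, half_lives_h, times_h, rel_noise = 0,
                           seed = 1L, mass_kg = 70, admin_MBq = 3700,
                           stimulation = c("rhTSH", "THW")) {
  stimulation <- match.arg(stimulation)
  if (length(fractions) != length(half_lives_h) ||
      !length(fractions) %in% 1:2)
    stop("1 or 2 components required, fractions matching half-lives")
  if (any(fractions <= 0)) stop("fractions must be positive")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (any(half_lives_h <= 0 | half_lives_h > i131_half_life_h()))
    stop(sprintf("half-lives must lie in (0, %g] h", i131_half_life_h()))
  if (any(diff(times_h) <= 0)) stop("measurement times must be strictly increasing")
  if (mass_kg <= 0) stop("patient mass must be > 0")
  if (admin_MBq <= 0) stop("administered activity must be > 0")
  if (rel_noise < 0) stop("rel_noise must be >= 0")
  structure(list(fractions = as.numeric(fractions),
                 half_lives_h = as.numeric(half_lives_h),
                 times_h = as.numeric(times_h), rel_noise = rel_noise,
                 seed = as.integer(seed), mass_kg = mass_kg,
                 admin_MBq = admin_MBq, stimulation = stimulation),
            class = "retention_spec")
}

#' Simulate a whole-body retention measurement series
#'
#' @param spec A [retention_spec()].
#' @return A list: `series` (data frame time_h, retained_MBq), `mass_kg`,
#'   `admin_MBq`, `stimulation`, and the analytic ground truth
#'   `true_tiac_h = sum(f_i * T_i) / ln 2`.
#' @export
make_retention_series <- function(spec) {
  stopifnot(inherits(spec, "retention_spec"))
  retained <- spec$admin_MBq *
    vapply(spec$times_h,
           function(t) sum(spec$fractions * 2^(-t / spec$half_lives_h)),
           numeric(1))
  if (spec$rel_noise > 0)
    retained <- with_seed(spec$seed,
      pmax(0, retained * (1 + rnorm(length(retained), sd = spec$rel_noise))))
  list(series = data.frame(time_h = spec$times_h, retained_MBq = retained),
       mass_kg = spec$mass_kg, admin_MBq = spec$admin_MBq,
       stimulation = spec$stimulation,
       true_tiac_h = sum(spec$fractions * spec$half_lives_h) / log(2))
}

#' Simulate a system calibration acquisition and a sphere recovery series
#'
#' The calibration acquisition is a uniform box of known activity imaged at
#' the stated sensitivity (total counts = activity x CF in the noise-free
#' case). The sphere series images spheres of increasing volume through the
#' same Gaussian resolution model; the ratio measured/true inside the true
#' sphere mask is the recovery coefficient, which decreases as the sphere
#' shrinks whenever sigma > 0.
#'
#' @param true_activity_MBq Activity in the calibration phantom (> 0).
#' @param true_cf_cps_per_MBq True system sensitivity.
#' @param sphere_volumes_ml Sphere volumes, strictly increasing, all > 0.
#' @param sigma_mm Gaussian resolution (partial-volume) blur.
#' @param spacing_mm Simulation grid spacing.
#' @param rel_noise Relative Gaussian noise on the measured sphere
#'   activities (0 = noise-free).
#' @param seed Seed for the noise.
#' @return A list: `calibration` (total_count_rate_cps, true_activity_MBq)
#'   and `spheres` (data frame volume_ml, measured_MBq, true_MBq).
#' @export
make_calibration_set <- function(true_activity_MBq, true_cf_cps_per_MBq,
                                 sphere_volumes_ml, sigma_mm = 0,
                                 spacing_mm = 2, rel_noise = 0, seed = 1L) {
  if (true_activity_MBq <= 0) stop("true activity must be > 0")
  if (true_cf_cps_per_MBq <= 0) stop("calibration factor must be > 0")
  if (any(sphere_volumes_ml <= 0)) stop("sphere volumes must be > 0")
  if (length(sphere_volumes_ml) > 1 && any(diff(sphere_volumes_ml) <= 0))
    stop("sphere volumes must be strictly increasing")
  measured <- true <- numeric(length(sphere_volumes_ml))
  for (i in seq_along(sphere_volumes_ml)) {
    v <- sphere_volumes_ml[i]
    r_mm <- (3 * v / (4 * pi))^(1 / 3) * 10
    margin <- 4 * sigma_mm + 4 * spacing_mm
    n <- as.integer(ceiling((2 * r_mm + 2 * margin) / spacing_mm))
    centre <- n * spacing_mm / 2
    org <- phantom_organ("sphere", "sphere", centre_mm = rep(centre, 3),
                         radii_mm = r_mm, conc_MBq_per_ml = 1,
                         t_eff_h = i131_half_life_h())
    mask <- .primitive_mask(org, rep(n, 3L), rep(spacing_mm, 3))
    act <- array(0, rep(n, 3L))
    act[mask] <- 1
    true[i] <- sum(mask) * voxel_volume_ml(rep(spacing_mm, 3))
    blurred <- if (sigma_mm > 0)
      gaussian_blur3(act, sigma_mm, rep(spacing_mm, 3)) else act
    measured[i] <- sum(blurred[mask]) * voxel_volume_ml(rep(spacing_mm, 3))
  }
  if (rel_noise > 0)
    measured <- with_seed(seed,
      pmax(0, measured * (1 + rnorm(length(measured), sd = rel_noise))))
  list(calibration = list(
         total_count_rate_cps = true_activity_MBq * true_cf_cps_per_MBq,
         true_activity_MBq = true_activity_MBq),
       spheres = data.frame(volume_ml = sphere_volumes_ml,
                            measured_MBq = measured, true_MBq = true))
}
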