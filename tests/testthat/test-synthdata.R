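# Digital phantom and acquisition generators: ground truth, voxelization,
# noise reproducibility, conservation under blur.

test_that("voxelized sphere volume and activity match the analytic primitive", {
  ph <- make_phantom(phantom_spec(
    shape = c(24, 24, 24), spacing_mm = 2,
    organs = list(phantom_organ("neck uptake", "sphere", c(23, 23, 23), 10,
                                conc_MBq_per_ml = 0.1, t_eff_h = 24))))
  analytic_vol <- 4 / 3 * pi * 1^3 # cm^3 for a 10 mm radius
  expect_lt(abs(ph$truth$volume_ml / analytic_vol - 1), 0.05)
  expect_lt(abs(ph$truth$activity_MBq / (0.1 * analytic_vol) - 1), 0.05)
  expect_equal(ph$truth$activity_MBq, 0.1 * ph$truth$volume_ml)
})

test_that("zero concentration yields exactly zero true activity", {
  ph <- make_phantom(phantom_spec(
    shape = c(16, 16, 16), spacing_mm = 4,
    organs = list(
      phantom_organ("liver", "sphere", c(20, 20, 20), 10, 0, 16),
      phantom_organ("spleen", "box", c(44, 44, 44), c(8, 8, 8), 0, 14))))
  expect_identical(ph$truth$activity_MBq, c(0, 0))
  expect_identical(ph$truth$dose_Gy, c(0, 0))
})

test_that("head/neck-only FOV drops the abdominal organs", {
  spec <- example_phantom_spec(fov = "head-neck-only")
  ph <- make_phantom(spec)
  expect_false(any(c("liver", "spleen", "left kidney", "right kidney",
                     "urinary bladder", "L2-L4") %in% names(ph$masks)))
  expect_true(all(c("neck uptake", "salivary glands", "left lung",
                    "right lung") %in% names(ph$masks)))
  expect_setequal(ph$truth$organ, names(ph$masks))
})

test_that("invalid phantoms are rejected with the offending organ named", {
  expect_error(phantom_spec(
    shape = c(10, 10, 10), spacing_mm = 2,
    organs = list(phantom_organ("liver", "sphere", c(2, 10, 10), 8, 0.1, 16))),
    "liver")
  expect_error(make_phantom(phantom_spec(
    shape = c(20, 20, 20), spacing_mm = 2,
    organs = list(
      phantom_organ("liver", "sphere", c(20, 20, 20), 8, 0.1, 16),
      phantom_organ("spleen", "sphere", c(24, 20, 20), 8, 0.1, 14)))),
    "overlap")
  expect_error(phantom_organ("neck uptake", "sphere", c(5, 5, 5), 2, 0.1,
                             t_eff_h = 200), "half-life")
})

test_that("masks are pairwise disjoint", {
  ph <- make_phantom(example_phantom_spec())
  total <- Reduce(`+`, lapply(ph$masks, as.numeric))
  expect_lte(max(total), 1)
})

test_that("noise-free series halve exactly per effective half-life", {
  ph <- small_phantom(conc = c(0.2, 0.05), t_eff = c(24, 24))
  ts <- make_timeseries(ph, acquisition_spec(c(24, 48), cf_cps_per_MBq = 1))
  for (org in names(ph$masks)) {
    a0 <- ph$truth$activity_MBq[ph$truth$organ == org]
    expect_equal(sum(ts[[1]]$data[ph$masks[[org]]]), 0.5 * a0,
                 tolerance = 1e-12)
    expect_equal(sum(ts[[2]]$data[ph$masks[[org]]]), 0.25 * a0,
                 tolerance = 1e-12)
  }
})

test_that("identical seeds reproduce bit-identical Poisson images", {
  ph <- small_phantom()
  acq <- acquisition_spec(c(24, 48), cf_cps_per_MBq = 1e5,
                          noise = "poisson", seed = 42)
  t1 <- make_timeseries(ph, acq)
  t2 <- make_timeseries(ph, acq)
  expect_identical(t1[[1]]$data, t2[[1]]$data)
  expect_identical(t1[[2]]$data, t2[[2]]$data)
  t3 <- make_timeseries(ph, acquisition_spec(c(24, 48), cf_cps_per_MBq = 1e5,
                                             noise = "poisson", seed = 43))
  expect_false(identical(t1[[1]]$data, t3[[1]]$data))
})

test_that("Gaussian blur loses activity inside the mask but conserves the grid total", {
  ph <- make_phantom(phantom_spec(
    shape = c(48, 48, 48), spacing_mm = 2,
    organs = list(phantom_organ("neck uptake", "sphere", c(48, 48, 48), 8,
                                0.1, 24))))
  sharp <- make_timeseries(ph, acquisition_spec(24))
  blurred <- make_timeseries(ph, acquisition_spec(24, sigma_mm = 8))
  mask <- ph$masks[["neck uptake"]]
  expect_lt(sum(blurred[[1]]$data[mask]), sum(sharp[[1]]$data[mask]))
  expect_lt(abs(sum(blurred[[1]]$data) / sum(sharp[[1]]$data) - 1), 1e-6)
})

test_that("time-points outside the plausible window are rejected", {
  expect_error(acquisition_spec(c(24, 400)), "360")
  expect_error(acquisition_spec(c(48, 24)), "increasing")
})

test_that("retention series sit on the model, anchor at A0, and are seed-reproducible", {
  spec <- retention_spec(c(0.6, 0.4), c(5, 24), times_h = c(0, 6, 24, 48),
                         admin_MBq = 1000)
  rs <- make_retention_series(spec)
  expect_equal(rs$series$retained_MBq[1], 1000)
  expect_equal(rs$series$retained_MBq,
               1000 * (0.6 * 2^(-rs$series$time_h / 5) +
                       0.4 * 2^(-rs$series$time_h / 24)))
  expect_equal(rs$true_tiac_h, (0.6 * 5 + 0.4 * 24) / log(2),
               tolerance = 1e-12)
  noisy1 <- make_retention_series(retention_spec(
    c(0.6, 0.4), c(5, 24), times_h = c(2, 24, 48), rel_noise = 0.05,
    seed = 9))
  noisy2 <- make_retention_series(retention_spec(
    c(0.6, 0.4), c(5, 24), times_h = c(2, 24, 48), rel_noise = 0.05,
    seed = 9))
  expect_identical(noisy1$series, noisy2$series)
})

test_that("pure physical decay is the limiting retention model", {
  spec <- retention_spec(1, i131_half_life_h(), times_h = c(24, 96, 168),
                         admin_MBq = 1)
  rs <- make_retention_series(spec)
  expect_equal(rs$series$retained_MBq, 2^(-c(24, 96, 168) / 192.5),
               tolerance = 1e-12)
})

test_that("schedule truncation changes the fit inputs, not the underlying TIAC", {
  long <- make_retention_series(retention_spec(
    c(0.6, 0.4), c(5, 24), times_h = c(2, 6, 24, 48, 96, 167)))
  short <- make_retention_series(retention_spec(
    c(0.6, 0.4), c(5, 24), times_h = c(2, 6, 24, 44)))
  expect_equal(long$true_tiac_h, short$true_tiac_h)
  expect_equal(nrow(short$series), 4)
})

test_that("fractions that do not sum to one are rejected", {
  expect_error(retention_spec(c(0.6, 0.5), c(5, 24), times_h = c(2, 24)),
               "sum to 1")
})

test_that("calibration set reproduces the sensitivity and recovery ordering", {
  cs <- make_calibration_set(120, 5000, c(1, 10, 100), sigma_mm = 0)
  expect_equal(cs$calibration$total_count_rate_cps, 6e5)
  expect_equal(cs$spheres$measured_MBq / cs$spheres$true_MBq, rep(1, 3))
  csb <- make_calibration_set(120, 5000, c(1, 10, 100), sigma_mm = 8)
  rc <- csb$spheres$measured_MBq / csb$spheres$true_MBq
  expect_true(all(diff(rc) > 0))
  expect_true(all(rc < 1))
  expect_error(make_calibration_set(-1, 5000, c(1, 10)), "> 0")
})
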