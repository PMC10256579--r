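# Exponential kinetic fitting: mono-exponential, single-time-point and
# whole-body retention TIA/TIAC.

test_that("two-point mono-exponential fit uses the closed form", {
  fit <- fit_monoexp(data.frame(time_h = c(24, 48),
                                activity_MBq = c(100, 50)))
  expect_equal(log(2) / fit$lambdas, 24, tolerance = 1e-12)
  expect_equal(fit$amplitudes, 200, tolerance = 1e-12)
  expect_equal(fit$tia_MBq_h, 200 * 24 / log(2), tolerance = 1e-12)
  expect_equal(fit$tia_MBq_h, 6924.96, tolerance = 1e-4)
})

test_that("noise-free multi-point samples are recovered exactly", {
  t <- c(10, 20, 30)
  fit <- fit_monoexp(data.frame(time_h = t, activity_MBq = 100 * 2^(-t / 10)))
  expect_equal(fit$amplitudes, 100, tolerance = 1e-8)
  expect_equal(fit$lambdas, log(2) / 10, tolerance = 1e-8)
  expect_equal(fit$tia_MBq_h, 100 * 10 / log(2), tolerance = 1e-8)
  expect_equal(fit$tia_MBq_h, 1442.70, tolerance = 1e-5)
})

test_that("fits slower than physical decay clamp to the physical bound and flag", {
  fit <- fit_monoexp(data.frame(time_h = c(10, 11),
                                activity_MBq = c(50, 50)))
  expect_equal(fit$lambdas, log(2) / i131_half_life_h())
  expect_true("half_life_clamped" %in% fit$flags)
})

test_that("non-decreasing activity over more than a day is flagged as uptake", {
  fit <- fit_monoexp(data.frame(time_h = c(6, 48),
                                activity_MBq = c(10, 12)))
  expect_true("uptake_suspected" %in% fit$flags)
})

test_that("fewer than two positive samples directs to single-time-point mode", {
  expect_error(fit_monoexp(data.frame(time_h = c(24, 48),
                                      activity_MBq = c(5, 0))),
               "single-time-point")
})

test_that("single-time-point extrapolation matches the closed form", {
  neck <- tiac_single_timepoint(5, 96, organ = "neck uptake",
                                admin_MBq = 3700)
  lambda <- log(2) / 68
  expect_equal(neck$amplitudes, 5 * exp(lambda * 96), tolerance = 1e-12)
  expect_equal(neck$tia_MBq_h, 5 * exp(lambda * 96) / lambda,
               tolerance = 1e-12)
  expect_equal(neck$tia_MBq_h, 1305.2, tolerance = 2e-4)
  expect_equal(neck$tiac_h, 0.3528, tolerance = 5e-4)
  parotid <- tiac_single_timepoint(20, 24, organ = "parotid", admin_MBq = 3700)
  expect_equal(parotid$tia_MBq_h, 1605, tolerance = 1e-3)
  zero <- tiac_single_timepoint(0, 24, organ = "parotid", admin_MBq = 3700)
  expect_equal(zero$tia_MBq_h, 0)
  expect_equal(zero$tiac_h, 0)
})

test_that("shipped half-life defaults carry the study's assumed values", {
  d <- half_life_defaults()
  expect_equal(unname(d["neck uptake"]), 68)
  expect_equal(unname(d["parotid"]), 9.3)
  expect_equal(unname(d["submandibular"]), 8.6)
  d2 <- half_life_defaults("whole-body" = 16.6)
  expect_equal(unname(d2["whole-body"]), 16.6)
  expect_error(tiac_single_timepoint(5, 24, organ = "liver", admin_MBq = 1),
               "liver")
})

test_that("single-time-point TIA grows with the assumed half-life", {
  # TIA(T) = A(t1) e^(lambda t1) / lambda increases with T precisely while
  # lambda * t1 < 1, i.e. t1 < T / ln 2: a longer assumed half-life adds
  # more tail than it removes from the back-extrapolated uptake.
  tias <- vapply(c(20, 40, 68, 120, 180), function(T)
    tiac_single_timepoint(5, 24, half_life_h = T, admin_MBq = 1)$tia_MBq_h,
    numeric(1))
  expect_true(all(diff(tias) > 0))
  # beyond that point the extrapolation effect dominates and the ordering
  # reverses: measuring at 48 h, a 10 h half-life implies a larger TIA than
  # a 20 h one
  late10 <- tiac_single_timepoint(5, 48, half_life_h = 10, admin_MBq = 1)
  late20 <- tiac_single_timepoint(5, 48, half_life_h = 20, admin_MBq = 1)
  expect_gt(late10$tia_MBq_h, late20$tia_MBq_h)
})

test_that("noise-free bi-exponential retention is recovered to 0.1%", {
  rs <- make_retention_series(retention_spec(
    c(0.6, 0.4), c(5, 24), times_h = c(2, 6, 12, 24, 48, 96, 144),
    admin_MBq = 1))
  fit <- fit_retention(rs)
  expect_length(fit$lambdas, 2)
  expect_equal(fit$tiac_h, (0.6 * 5 + 0.4 * 24) / log(2), tolerance = 1e-3)
  expect_equal(sort(log(2) / fit$lambdas), c(5, 24), tolerance = 1e-3)
  expect_equal(fit$amplitudes / 1, c(0.6, 0.4), tolerance = 1e-3)
  expect_equal(sum(fit$amplitudes), 1, tolerance = 1e-12) # anchored to A0
})

test_that("mono-exponential retention falls back to one component", {
  rs <- make_retention_series(retention_spec(
    1, 11.5, times_h = c(2, 6, 24, 48, 96), admin_MBq = 1))
  fit <- fit_retention(rs, n_components = 2)
  expect_length(fit$lambdas, 1)
  expect_equal(fit$tiac_h, 11.5 / log(2), tolerance = 1e-6)
  expect_equal(fit$tiac_h, 16.590, tolerance = 1e-4)
})

test_that("truncated and full counting windows give the same noise-free TIAC", {
  long <- fit_retention(make_retention_series(retention_spec(
    c(0.6, 0.4), c(5, 24), times_h = c(2, 6, 24, 48, 96, 167))))
  short <- fit_retention(make_retention_series(retention_spec(
    c(0.6, 0.4), c(5, 24), times_h = c(2, 6, 24, 44))))
  expect_lt(abs(long$tiac_h / short$tiac_h - 1), 0.005)
})

test_that("degenerate retention inputs are rejected", {
  expect_error(fit_retention(data.frame(time_h = c(2, 24, 48),
                                        retained_MBq = c(0, 0, 0)),
                             admin_MBq = 1), "all-zero")
  expect_error(fit_retention(data.frame(time_h = c(2, 24),
                                        retained_MBq = c(1, 0.5))),
               "A0")
})

test_that("TIAC error under 5% noise stays small in the median", {
  errs <- vapply(1:25, function(s) {
    rs <- make_retention_series(retention_spec(
      c(0.6, 0.4), c(5, 24), times_h = c(2, 6, 12, 24, 48, 96, 120, 168),
      rel_noise = 0.05, seed = s, admin_MBq = 1))
    abs(fit_retention(rs)$tiac_h / rs$true_tiac_h - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("TIA equals adaptive quadrature of the fitted model", {
  fits <- list(
    fit_monoexp(data.frame(time_h = c(24, 48), activity_MBq = c(100, 50))),
    tiac_single_timepoint(5, 96, organ = "neck uptake", admin_MBq = 3700),
    fit_retention(make_retention_series(retention_spec(
      c(0.6, 0.4), c(5, 24), times_h = c(2, 6, 24, 48, 96)))))
  for (fit in fits)
    expect_lt(abs(fit$tia_MBq_h / tia_by_quadrature(fit) - 1), 1e-6)
})

test_that("single-time-point with the true half-life reproduces the 2-point fit", {
  fit <- fit_monoexp(data.frame(time_h = c(24, 48),
                                activity_MBq = c(80, 40)))
  for (i in 1:2) {
    stp <- tiac_single_timepoint(c(80, 40)[i], c(24, 48)[i],
                                 half_life_h = log(2) / fit$lambdas,
                                 admin_MBq = 3700)
    expect_equal(stp$tia_MBq_h, fit$tia_MBq_h, tolerance = 1e-12)
  }
})

test_that("kinetic_fit methods behave as a fitted model", {
  ser <- data.frame(time_h = c(6, 24, 48), activity_MBq = 50 * 2^(-c(6, 24, 48) / 12))
  fit <- fit_monoexp(ser, admin_MBq = 1000, organ = "neck uptake")
  expect_named(coef(fit), c("a1", "lambda1"))
  expect_equal(predict(fit, 0), sum(fit$amplitudes))
  expect_equal(fitted(fit), predict(fit, ser$time_h))
  expect_equal(residuals(fit), ser$activity_MBq - fitted(fit),
               tolerance = 1e-9)
  expect_output(print(fit), "TIAC")
  expect_output(print(summary(fit)), "RSS")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(3L, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
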