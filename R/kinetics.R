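## Exponential kinetic fitting: mono-exponential organ washout,
## single-time-point extrapolation with fixed effective half-lives, and
## constrained multi-exponential whole-body retention fits. Every fit
## returns a `kinetic_fit` object whose time-integrated activity (TIA,
## integration from t = 0 to infinity assuming instantaneous uptake at
## administration) and TIAC (TIA / administered activity, hours) are
## available in closed form.

.lambda_min <- function() log(2) / i131_half_life_h() # slowest physical decay
.lambda_max <- function() log(2) / 0.5                # 30-min half-life floor

new_kinetic_fit <- function(amplitudes, lambdas, model,
                            admin_MBq = NA_real_, organ = NA_character_,
                            flags = character(), rss = NA_real_,
                            data = NULL) {
  stopifnot(length(amplitudes) == length(lambdas), all(lambdas > 0),
            all(amplitudes >= 0))
  ord <- order(lambdas, decreasing = TRUE) # faster component first
  amplitudes <- amplitudes[ord]
  lambdas <- lambdas[ord]
  tia <- sum(amplitudes / lambdas)
  structure(list(
    amplitudes = as.numeric(amplitudes), lambdas = as.numeric(lambdas),
    model = model, tia_MBq_h = tia,
    tiac_h = if (is.na(admin_MBq)) NA_real_ else tia / admin_MBq,
    admin_MBq = admin_MBq, organ = organ, flags = flags, rss = rss,
    n = if (is.null(data)) NA_integer_ else nrow(data), data = data),
    class = "kinetic_fit")
}

## ---- mono-exponential core shared by activity and dose-rate fitting ------

## Closed form for 2 points, weighted log-linear LS + unweighted nonlinear
## refinement for > 2; decay constants slower than physical decay are
## clamped with a flag and the amplitude re-estimated by linear LS at the
## clamped rate.
.fit_mono_core <- function(t, y) {
  flags <- character()
  keep <- y > 0
  if (sum(keep) < 2L)
    stop("fewer than 2 positive samples: use single-time-point mode ",
         "(tiac_single_timepoint) with an assumed effective half-life")
  t <- t[keep]; y <- y[keep]
  n <- length(t)
  if (!is.unsorted(y, strictly = FALSE) && diff(range(t)) > 24)
    flags <- c(flags, "uptake_suspected")
  if (n == 2L) {
    lambda <- log(y[1] / y[2]) / (t[2] - t[1])
    a0 <- y[1] * exp(lambda * t[1])
  } else {
    lf <- stats::lm(log(y) ~ t, weights = y)
    lambda <- -unname(stats::coef(lf)[2])
    a0 <- exp(unname(stats::coef(lf)[1]))
    if (lambda > 0) {
      ref <- tryCatch(
        minpack.lm::nlsLM(y ~ a * exp(-l * t),
                          start = list(a = a0, l = lambda),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(ref)) {
        cf <- stats::coef(ref)
        if (cf[["l"]] > 0 && cf[["a"]] > 0) {
          a0 <- cf[["a"]]; lambda <- cf[["l"]]
        }
      }
    }
  }
  if (lambda < .lambda_min()) {
    lambda <- .lambda_min()
    a0 <- sum(y * exp(-lambda * t)) / sum(exp(-2 * lambda * t))
    flags <- c(flags, "half_life_clamped")
  }
  rss <- sum((y - a0 * exp(-lambda * t))^2)
  list(a0 = a0, lambda = lambda, rss = rss, flags = flags, n = n)
}

#' Fit a mono-exponential washout to a time-activity series
#'
#' For exactly two points the closed-form solution is used
#' (`lambda = log(A1/A2) / (t2 - t1)`); for more, a log-linear least-squares
#' fit weighted by activity initialises an unweighted nonlinear
#' least-squares refinement on the linear scale. Effective half-lives longer
#' than the physical half-life of I-131 are unphysical: such fits are
#' clamped to the physical bound and flagged (`"half_life_clamped"`), and
#' series that do not decrease over a span of more than 24 h are flagged
#' (`"uptake_suspected"`) but still returned. TIA = A(0)/lambda.
#'
#' @param series A [time_activity_series()], or a data frame with columns
#'   `time_h` and `activity_MBq` (at least 2 positive samples).
#' @param admin_MBq Administered activity; defaults to the series attribute.
#' @param organ Organ label; defaults to the series attribute.
#' @return A `kinetic_fit` (see [predict.kinetic_fit()] and friends).
#' @examples
#' fit <- fit_monoexp(data.frame(time_h = c(24, 48),
#'                               activity_MBq = c(100, 50)))
#' fit$tia_MBq_h # 6924.96: A(0) = 200 MBq, T_eff = 24 h
#' @export
fit_monoexp <- function(series, admin_MBq = attr(series, "admin_MBq"),
                        organ = attr(series, "organ")) {
  core <- .fit_mono_core(series$time_h, series$activity_MBq)
  new_kinetic_fit(core$a0, core$lambda, model = "monoexp",
                  admin_MBq = admin_MBq %||% NA_real_,
                  organ = organ %||% NA_character_,
                  flags = core$flags, rss = core$rss,
                  data = data.frame(time_h = series$time_h,
                                    y = series$activity_MBq))
}

#' Shipped effective half-life defaults for single-time-point dosimetry
#'
#' Literature-derived effective half-lives used when only one imaging
#' time-point is available: 68 h for the neck uptake region (rhTSH-treated
#' populations) and 9.3 / 8.6 h for the parotid and submandibular salivary
#' glands. For other organs the patient's fitted whole-body effective
#' half-life is conventionally supplied explicitly.
#'
#' @param ... Named overrides or additions, hours, each in
#'   (0, [i131_half_life_h()]\].
#' @return Named numeric vector of effective half-lives (h).
#' @export
half_life_defaults <- function(...) {
  out <- c("neck uptake" = 68, "parotid" = 9.3, "submandibular" = 8.6)
  ov <- c(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("overrides must be named")
    out[names(ov)] <- ov
  }
  if (any(out <= 0 | out > i131_half_life_h()))
    stop(sprintf("half-lives must lie in (0, %g] h", i131_half_life_h()))
  out
}

#' Single-time-point TIA from an assumed effective half-life
#'
#' Extrapolates one measured activity back to administration with an
#' assumed effective half-life (organ default or an explicit value such as
#' the patient's fitted whole-body half-life):
#' `A(0) = A(t1) * exp(lambda * t1)`, `TIA = A(0)/lambda`,
#' `TIAC = TIA/A0`.
#'
#' @param activity_MBq Measured activity at `time_h` (>= 0; 0 gives a zero
#'   TIA).
#' @param time_h Measurement time, hours post administration (> 0).
#' @param organ Organ label used to look up `defaults`.
#' @param defaults Named half-life table, see [half_life_defaults()].
#' @param admin_MBq Administered activity A0.
#' @param half_life_h Explicit effective half-life overriding the lookup.
#' @return A `kinetic_fit` with model `"single-timepoint"`.
#' @examples
#' f <- tiac_single_timepoint(5, 96, organ = "neck uptake", admin_MBq = 3700)
#' c(f$tia_MBq_h, f$tiac_h) # about 1305 MBq h and 0.353 h
#' @export
tiac_single_timepoint <- function(activity_MBq, time_h,
                                  organ = NA_character_,
                                  defaults = half_life_defaults(),
                                  admin_MBq = NA_real_,
                                  half_life_h = NULL) {
  if (time_h <= 0) stop("measurement time must be > 0")
  if (activity_MBq < 0) stop("activity must be >= 0")
  t_eff <- if (!is.null(half_life_h)) half_life_h
           else if (!is.na(organ) && organ %in% names(defaults))
             unname(defaults[[organ]])
           else stop(sprintf(
             "no assumed effective half-life available for organ '%s'",
             organ))
  if (t_eff <= 0 || t_eff > i131_half_life_h())
    stop(sprintf("half-life must lie in (0, %g] h", i131_half_life_h()))
  lambda <- log(2) / t_eff
  a0 <- activity_MBq * exp(lambda * time_h)
  new_kinetic_fit(a0, lambda, model = "single-timepoint",
                  admin_MBq = admin_MBq, organ = organ, rss = 0,
                  data = data.frame(time_h = time_h, y = activity_MBq))
}

## ---- whole-body retention fitting ---------------------------------------

.retention_rss <- function(par, t, y, admin) {
  f <- par[1]
  pred <- admin * (f * exp(-par[2] * t) + (1 - f) * exp(-par[3] * t))
  sum((pred - y)^2)
}

#' Fit a whole-body retention curve with 1 or 2 exponential components
#'
#' Constrained nonlinear least squares anchored to the administered
#' activity: amplitudes are non-negative and sum to A0 (retention = 100% at
#' administration), and every decay constant lies between physical I-131
#' decay and a 30-minute half-life. The 2-component fit uses a deterministic
#' multi-start over half-life pairs drawn from \{2, 8, 24, 96\} h followed by
#' bounded Levenberg-Marquardt refinement, and falls back to 1 component
#' when fewer than 4 points are available or when the second component does
#' not reduce the residual sum of squares by at least 5%. The faster
#' component is reported first. TIA = sum(a_i / lambda_i).
#'
#' @param retention Data frame with columns `time_h`, `retained_MBq` (or the
#'   output of [make_retention_series()]).
#' @param admin_MBq Administered activity A0 anchoring the fit; taken from a
#'   [make_retention_series()] object automatically.
#' @param n_components 1 or 2.
#' @return A `kinetic_fit` with model `"retention"`.
#' @examples
#' rs <- make_retention_series(retention_spec(c(0.6, 0.4), c(5, 24),
#'                                            times_h = c(2, 6, 24, 48, 96)))
#' fit_retention(rs)$tiac_h # 18.178 h
#' @export
fit_retention <- function(retention, admin_MBq = NULL, n_components = 2) {
  if (is.list(retention) && !is.data.frame(retention) &&
      !is.null(retention$series)) {
    admin_MBq <- admin_MBq %||% retention$admin_MBq
    retention <- retention$series
  }
  if (is.null(admin_MBq) || is.na(admin_MBq) || admin_MBq <= 0)
    stop("administered activity A0 (> 0) is required to anchor the fit")
  if (!all(c("time_h", "retained_MBq") %in% names(retention)))
    stop("retention needs columns time_h and retained_MBq")
  if (!n_components %in% 1:2) stop("n_components must be 1 or 2")
  t <- retention$time_h
  y <- retention$retained_MBq
  if (all(y == 0)) stop("all-zero retention cannot be fitted")
  if (length(t) < n_components + 1L)
    stop(sprintf("at least %d data points are needed for %d component(s)",
                 n_components + 1L, n_components))
  lo <- .lambda_min(); hi <- .lambda_max()

  fit1 <- stats::optimize(function(l) sum((admin_MBq * exp(-l * t) - y)^2),
                          interval = c(lo, hi), tol = 1e-12)
  rss1 <- fit1$objective

  make1 <- function(flags = character()) {
    l1 <- fit1$minimum
    fl <- flags
    if (l1 <= lo * (1 + 1e-9)) fl <- c(fl, "half_life_clamped")
    new_kinetic_fit(admin_MBq, l1, model = "retention",
                    admin_MBq = admin_MBq, organ = "whole-body",
                    flags = fl, rss = rss1,
                    data = data.frame(time_h = t, y = y))
  }
  if (n_components == 1L || length(t) < 4L) return(make1())

  grid_T <- c(2, 8, 24, 96)
  best <- NULL
  for (i in seq_along(grid_T)) for (j in seq_along(grid_T)) {
    if (grid_T[i] >= grid_T[j]) next # fast component first
    par0 <- c(0.5, log(2) / grid_T[i], log(2) / grid_T[j])
    opt <- stats::optim(par0, .retention_rss, t = t, y = y, admin = admin_MBq,
                        method = "L-BFGS-B",
                        lower = c(1e-6, lo, lo), upper = c(1 - 1e-6, hi, hi),
                        control = list(factr = 1e1, maxit = 500))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  ## bounded Levenberg-Marquardt polish from the best grid start
  df <- data.frame(t = t, y = y)
  ref <- tryCatch(
    minpack.lm::nlsLM(
      y ~ admin_MBq * (f * exp(-l1 * t) + (1 - f) * exp(-l2 * t)),
      data = df,
      start = list(f = best$par[1], l1 = best$par[2], l2 = best$par[3]),
      lower = c(1e-6, lo, lo), upper = c(1 - 1e-6, hi, hi),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) NULL)
  par2 <- best$par
  rss2 <- best$value
  if (!is.null(ref)) {
    cf <- stats::coef(ref)
    rss_ref <- sum(stats::resid(ref)^2)
    if (rss_ref <= rss2) {
      par2 <- unname(cf[c("f", "l1", "l2")])
      rss2 <- rss_ref
    }
  }
  ## fallback: second component must buy >= 5% RSS; a near-perfect
  ## 1-component fit (relative to the signal) is also kept mono.
  if (rss1 <= 1e-12 * sum(y^2) || rss2 > 0.95 * rss1) return(make1())
  a <- admin_MBq * c(par2[1], 1 - par2[1])
  l <- par2[2:3]
  flags <- if (any(l <= lo * (1 + 1e-9))) "half_life_clamped" else character()
  new_kinetic_fit(a, l, model = "retention", admin_MBq = admin_MBq,
                  organ = "whole-body", flags = flags, rss = rss2,
                  data = data.frame(time_h = t, y = y))
}

## ---- methods -------------------------------------------------------------

#' Methods for kinetic fits
#'
#' A `kinetic_fit` holds 1-2 exponential components (amplitude in the units
#' of the fitted quantity, decay constant in 1/h), the closed-form
#' time-integrated activity and, when the administered activity is known,
#' the TIAC. `predict()` evaluates the fitted model at arbitrary times;
#' `coef()` returns the named parameter vector; `simulate()` draws new
#' series at the fitted time-points with multiplicative Gaussian noise
#' scaled by the residual standard deviation.
#'
#' @param object,x A `kinetic_fit`.
#' @param times_h Times (hours) at which to evaluate the fitted model;
#'   defaults to the fitted time-points.
#' @param nsim,seed Number of simulated series and RNG seed.
#' @param ... Unused.
#' @return `predict()` a numeric vector; `coef()` a named vector
#'   `a1, lambda1[, a2, lambda2]`; `simulate()` a data frame of `nsim`
#'   series columns.
#' @name kinetic_fit-methods
NULL

#' @rdname kinetic_fit-methods
#' @export
predict.kinetic_fit <- function(object, times_h = NULL, ...) {
  if (is.null(times_h)) times_h <- object$data$time_h
  vapply(times_h,
         function(t) sum(object$amplitudes * exp(-object$lambdas * t)),
         numeric(1))
}

#' @rdname kinetic_fit-methods
#' @export
coef.kinetic_fit <- function(object, ...) {
  k <- length(object$amplitudes)
  stats::setNames(c(rbind(object$amplitudes, object$lambdas)),
                  c(rbind(paste0("a", seq_len(k)),
                          paste0("lambda", seq_len(k)))))
}

#' @rdname kinetic_fit-methods
#' @export
fitted.kinetic_fit <- function(object, ...) predict(object)

#' @rdname kinetic_fit-methods
#' @export
residuals.kinetic_fit <- function(object, ...) {
  if (is.null(object$data)) return(numeric(0))
  object$data$y - predict(object)
}

#' @rdname kinetic_fit-methods
#' @export
simulate.kinetic_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- predict(object)
  sdr <- if (!is.na(object$rss) && object$n > length(object$amplitudes) * 2)
    sqrt(object$rss / (object$n - length(object$amplitudes) * 2)) else 0
  rel <- if (mean(mu) > 0) sdr / mean(mu) else 0
  draw <- function() pmax(0, mu * (1 + stats::rnorm(length(mu), sd = rel)))
  sims <- if (is.null(seed)) replicate(nsim, draw())
          else with_seed(seed, replicate(nsim, draw()))
  out <- as.data.frame(matrix(sims, nrow = length(mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @rdname kinetic_fit-methods
#' @export
print.kinetic_fit <- function(x, ...) {
  k <- length(x$amplitudes)
  cat(sprintf("<kinetic_fit> %s, %d component(s)%s\n", x$model, k,
              if (!is.na(x$organ)) sprintf(", organ '%s'", x$organ) else ""))
  for (i in seq_len(k))
    cat(sprintf("  a%d = %g, lambda%d = %g /h (T_eff = %.3g h)\n",
                i, x$amplitudes[i], i, x$lambdas[i], log(2) / x$lambdas[i]))
  cat(sprintf("  TIA = %g MBq h", x$tia_MBq_h))
  if (!is.na(x$tiac_h)) cat(sprintf(", TIAC = %g h", x$tiac_h))
  cat("\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname kinetic_fit-methods
#' @export
summary.kinetic_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.kinetic_fit")
}

#' @export
print.summary.kinetic_fit <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  if (!is.na(f$rss))
    cat(sprintf("  RSS = %g over %d point(s)\n", f$rss, f$n))
  if (!is.null(f$data) && nrow(f$data)) {
    cat("  residuals:\n")
    print(summary(residuals(f)))
  }
  invisible(x)
}

#' @rdname kinetic_fit-methods
#' @export
plot.kinetic_fit <- function(x, ...) {
  if (is.null(x$data) || !nrow(x$data)) stop("fit carries no data to plot")
  tt <- seq(0, max(x$data$time_h) * 1.2, length.out = 200)
  graphics::plot(x$data$time_h, x$data$y, pch = 16,
                 xlab = "time post administration (h)",
                 ylab = "activity (MBq)",
                 main = sprintf("%s fit%s", x$model,
                                if (!is.na(x$organ))
                                  sprintf(" - %s", x$organ) else ""), ...)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}
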