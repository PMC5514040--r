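#' Fit a linear peak trajectory
#'
#' Ordinary least squares of component peak positions against chase time.
#' The migration speed is the absolute slope; the sign only encodes
#' direction (centrifugal = away from the ILC, increasing radial index;
#' centripetal = towards the ILC).
#'
#' @param times Chase times in days (at least two distinct values).
#' @param locations Peak radial indices, one per time.
#' @return A `trajectory_fit`: list with `slope` (radial indices/day,
#'   signed), `intercept` (radial index at day 0), `r_squared` (`NA` with
#'   fewer than 3 points), `speed` (`abs(slope)`) and `direction`.
#' @examples
#' fit_trajectory(c(1, 4, 21), c(1.17, 1.07, 0.82))  # SNS stream, ~0.017/d
#' @export
fit_trajectory <- function(times, locations) {
  stopifnot(length(times) == length(locations), length(times) >= 2)
  if (length(unique(times)) < 2) {
    stop("singular design: at least two distinct times required",
         call. = FALSE)
  }
  fit <- stats::lm(locations ~ times)
  cf <- unname(stats::coef(fit))
  r2 <- if (length(times) >= 3) {
    tss <- sum((locations - mean(locations))^2)
    if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else NA_real_
  } else {
    NA_real_
  }
  structure(
    list(slope = cf[2], intercept = cf[1], r_squared = r2,
         speed = abs(cf[2]),
         direction = if (cf[2] > 0) "centrifugal" else "centripetal",
         times = times, locations = locations),
    class = "trajectory_fit"
  )
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("Peak trajectory: y = %.4gx + %.4g (R^2: %s); speed %.4g radial indices/d, %s\n",
              x$slope, x$intercept,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared)),
              x$speed, x$direction))
  invisible(x)
}

#' Fit dispersion growth over time
#'
#' OLS of component standard deviations against chase time, describing how
#' a cohort's positional spread grows as it invades the sensory OE.
#'
#' @param times Chase times in days.
#' @param sigmas Component standard deviations (radial indices).
#' @return A `dispersion_fit`: list with `rate` (sigma units/day),
#'   `baseline` (sigma at day 0) and `r_squared`.
#' @examples
#' fit_dispersion(c(1, 4, 21), 0.0701 + 0.0024 * c(1, 4, 21))
#' @export
fit_dispersion <- function(times, sigmas) {
  tr <- fit_trajectory(times, sigmas)
  structure(
    list(rate = tr$slope, baseline = tr$intercept,
         r_squared = tr$r_squared, times = times, sigmas = sigmas),
    class = "dispersion_fit"
  )
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat(sprintf("Dispersion growth: sigma = %.4gx + %.4g (R^2: %s)\n",
              x$rate, x$baseline,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared))))
  invisible(x)
}

#' Half-life and mean lifespan from an exponential decay rate
#'
#' @param decay_rate Exponential decay rate per day (positive).
#' @return Named vector `c(half_life, mean_lifespan)` in days:
#'   `log(2)/decay_rate` and `1/decay_rate`.
#' @examples
#' lifespan_summary(0.035)  # ~19.8 d half-life, ~28.6 d mean lifespan
#' @export
lifespan_summary <- function(decay_rate) {
  if (!is.finite(decay_rate) || decay_rate <= 0) {
    stop("`decay_rate` must be positive", call. = FALSE)
  }
  c(half_life = log(2) / decay_rate, mean_lifespan = 1 / decay_rate)
}

#' Fit an exponential survival curve to labelled-cell counts
#'
#' Nonlinear least squares of `count = A * exp(-lambda * t)`, initialized
#' from a log-linear OLS fit. Double-labelled OSN counts rise until the
#' cohort matures (about 4 days) and decay afterwards; `exclude_rise` drops
#' all timepoints before the observed count maximum so only the decay phase
#' is fitted.
#'
#' @param times Chase times in days.
#' @param counts Positive cell counts per section.
#' @param exclude_rise Drop timepoints before the count maximum (default
#'   `TRUE`).
#' @return A `survival_fit`: list with `amplitude`, `decay_rate`,
#'   `half_life`, `mean_lifespan`, `r_squared`, `fitted_timepoints`.
#' @examples
#' t <- c(4, 8, 30, 90)
#' fit_survival(t, 387.5 * exp(-0.035 * t))
#' @export
fit_survival <- function(times, counts, exclude_rise = TRUE) {
  stopifnot(length(times) == length(counts))
  if (any(counts <= 0)) {
    stop("`counts` must be positive", call. = FALSE)
  }
  ord <- order(times)
  times <- times[ord]
  counts <- counts[ord]
  keep <- if (exclude_rise) seq(which.max(counts), length(times)) else
    seq_along(times)
  if (length(keep) < 3) {
    stop("insufficient data: at least 3 timepoints required after ",
         "excluding the rise", call. = FALSE)
  }
  t_ <- times[keep]
  c_ <- counts[keep]
  ols <- stats::lm(log(c_) ~ t_)
  start <- list(A = exp(unname(stats::coef(ols)[1])),
                lambda = max(-unname(stats::coef(ols)[2]), 1e-6))
  nls_fit <- minpack.lm::nlsLM(c_ ~ A * exp(-lambda * t_), start = start,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  est <- stats::coef(nls_fit)
  lambda <- unname(est["lambda"])
  if (lambda <= 0) {
    stop("survival fit produced a non-positive decay rate", call. = FALSE)
  }
  rss <- sum(stats::resid(nls_fit)^2)
  tss <- sum((c_ - mean(c_))^2)
  structure(
    list(amplitude = unname(est["A"]), decay_rate = lambda,
         half_life = log(2) / lambda, mean_lifespan = 1 / lambda,
         r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
         fitted_timepoints = t_, fitted_counts = c_),
    class = "survival_fit"
  )
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("Survival: #cells = %.4g e^(-%.4g t) (R^2: %s)\n",
              x$amplitude, x$decay_rate,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared))))
  cat(sprintf("  half-life %.3g d, mean lifespan %.3g d (fitted at t = %s)\n",
              x$half_life, x$mean_lifespan,
              paste(x$fitted_timepoints, collapse = ", ")))
  invisible(x)
}

#' Radial distance traversed over a mean lifespan
#'
#' @param speed Migration speed in radial indices per day (>= 0).
#' @param mean_lifespan Mean lifespan in days (> 0).
#' @return `speed * mean_lifespan`, in radial indices. At the measured
#'   average speed and lifespan this is about half the sensory OE.
#' @examples
#' traversal_distance(0.017, 28.6)
#' @export
traversal_distance <- function(speed, mean_lifespan) {
  stopifnot(speed >= 0)
  if (mean_lifespan <= 0) stop("`mean_lifespan` must be positive",
                               call. = FALSE)
  speed * mean_lifespan
}

#' Daily cell production of one olfactory epithelium
#'
#' Extrapolates the mean number of newly labelled cells per cross section to
#' the whole OE.
#'
#' @param cells_per_section Mean labelled cells per section after a 24 h
#'   pulse.
#' @param n_sections Number of consecutive cross sections spanning the OE.
#' @return Estimated new cells per OE per day.
#' @examples
#' daily_production(478.8, 25)  # ~12,000 new cells per day
#' @export
daily_production <- function(cells_per_section, n_sections) {
  stopifnot(cells_per_section >= 0, n_sections >= 1)
  cells_per_section * n_sections
}
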