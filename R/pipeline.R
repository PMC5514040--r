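# data-driven initial component locations: modes of a kernel density
# estimate, augmented with sample quantiles when fewer than k modes exist
.peak_init <- function(x, k) {
  d <- stats::density(x, n = 512)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  peaks <- d$x[is_max][order(y[is_max], decreasing = TRUE)]
  peaks <- peaks[peaks > 0]
  init <- sort(utils::head(peaks, k))
  if (length(init) < k) {
    extra <- stats::quantile(x, probs = seq_len(k) / (k + 1), names = FALSE)
    for (e in extra) {
      if (length(init) >= k) break
      if (all(abs(init - e) > stats::sd(x) / (2 * k))) {
        init <- sort(c(init, e))
      }
    }
    while (length(init) < k) {
      init <- sort(c(init, stats::median(x) * stats::runif(1, 0.8, 1.2)))
    }
  }
  init
}

#' Recover migration, dispersion, survival and birth-bias parameters from a
#' pulse-chase series
#'
#' Runs the full analysis chain on a table of labelled-cell positions across
#' chase timepoints: per-timepoint mixture unmixing ([em_fit()]), component
#' tracking across timepoints, trajectory and dispersion regressions
#' ([fit_trajectory()], [fit_dispersion()]), exponential decay of the moving
#' cohort, and the ILC:SNS birth ratio.
#'
#' Component roles are assigned by position order: the last component is the
#' stationary peripheral population, the second-to-last the SNS stream, and
#' the lowest component(s) the ILC side. Early timepoints are fitted with
#' `k = 3` (the stationary ILC progenitors and the young ILC cohort are not
#' yet separable); timepoints at or beyond `split_day` with `k = 4`, where
#' the moving ILC cohort has detached from the stationary progenitors.
#'
#' Because the merged early ILC component mixes the moving cohort with the
#' stationary progenitors, its mean is biased towards the progenitor
#' location. With `decontaminate_ilc = TRUE` the progenitor population's
#' (constant) cell count and location are estimated from the `k = 4`
#' timepoints and subtracted from the merged components before the ILC
#' trajectory and the decay rate are fitted.
#'
#' The dispersion-growth rate is estimated from the SNS stream, whose
#' components are uncontaminated at all timepoints.
#'
#' @param cells Data frame with `radial_index` and `chase_days` columns
#'   (e.g. from [simulate_pulse_chase()] or [read_cell_observations()]).
#' @param family `"mixed"` (default) fits the lowest (ILC/progenitor-side)
#'   component as lognormal -- distributions at the tissue origin are
#'   strongly right-skewed -- and the moving and peripheral components as
#'   Gaussian, whose drifted, dispersion-broadened shapes are close to
#'   symmetric; `"lognormal"` or `"gaussian"` force a single family.
#' @param split_day Chase day from which `k = 4` components are fitted.
#' @param k_by_day Optional named vector overriding the number of components
#'   per chase day (names = chase days).
#' @param init_by_day Optional named list of manual initial component
#'   locations per chase day; defaults to density-mode initialization.
#' @param maturation_days Maturation time; timepoints from this day onward
#'   enter the decay fit.
#' @param decontaminate_ilc Subtract the estimated stationary-progenitor
#'   contribution from merged early ILC components.
#' @param seed Integer seed for the mixture fits.
#' @return A `kinetics_recovery`: list with `mixtures` (per-day fits),
#'   `components` (tidy per-day component table with assigned roles),
#'   `ilc_trajectory`, `sns_trajectory`, `dispersion` (SNS stream),
#'   `decay_rate`, `half_life`, `mean_lifespan`, `birth_ratio`
#'   (ILC:SNS of the moving cohorts) and `moving_counts`.
#' @examples
#' \donttest{
#' sim <- simulate_pulse_chase(generator_truth(), n_cells = 5000, seed = 2)
#' recover_kinetics(sim$cells, seed = 2)
#' }
#' @export
recover_kinetics <- function(cells,
                             family = c("mixed", "lognormal", "gaussian"),
                             split_day = 10, k_by_day = NULL,
                             init_by_day = NULL, maturation_days = 4,
                             decontaminate_ilc = TRUE, seed = 1) {
  family <- match.arg(family)
  stopifnot(all(c("radial_index", "chase_days") %in% names(cells)))
  days <- sort(unique(cells$chase_days))
  if (length(days) < 2) {
    stop("at least two chase timepoints required", call. = FALSE)
  }

  fits <- list()
  rows <- list()
  for (d in days) {
    x <- cells$radial_index[cells$chase_days == d]
    k <- if (!is.null(k_by_day) && as.character(d) %in% names(k_by_day)) {
      as.integer(k_by_day[[as.character(d)]])
    } else if (d >= split_day) 4L else 3L
    init <- if (!is.null(init_by_day) &&
                as.character(d) %in% names(init_by_day)) {
      init_by_day[[as.character(d)]]
    } else {
      .peak_init(x[x > 0], k)
    }
    day_family <- if (family == "mixed") {
      c("lognormal", rep("gaussian", k - 1))
    } else {
      family
    }
    fit <- em_fit(x, k = k, family = day_family, init = "manual",
                  init_locations = init, seed = seed)
    fits[[as.character(d)]] <- fit
    comp <- fit$components
    role <- rep("ilc_merged", k)
    role[k] <- "peripheral"
    role[k - 1] <- "sns"
    if (k >= 4) {
      role[1] <- "ilc_stationary"
      role[2] <- "ilc_moving"
    }
    rows[[as.character(d)]] <- data.frame(
      chase_days = d, component = comp$component, role = role,
      weight = comp$weight, location = comp$location,
      dispersion = comp$dispersion, n_cells = length(x)
    )
  }
  comps <- do.call(rbind, rows)
  rownames(comps) <- NULL

  # stationary-progenitor estimate from the k = 4 timepoints
  stat <- comps[comps$role == "ilc_stationary", , drop = FALSE]
  stat_count <- if (nrow(stat) > 0) mean(stat$weight * stat$n_cells) else 0
  stat_mean <- if (nrow(stat) > 0) mean(stat$location) else NA_real_

  ilc_pts <- do.call(rbind, lapply(split(comps, comps$chase_days), function(cc) {
    mv <- cc[cc$role == "ilc_moving", , drop = FALSE]
    if (nrow(mv) == 1) {
      return(data.frame(chase_days = mv$chase_days, location = mv$location,
                        count = mv$weight * mv$n_cells))
    }
    mg <- cc[cc$role == "ilc_merged", , drop = FALSE][1, ]
    cnt <- mg$weight * mg$n_cells
    loc <- mg$location
    if (decontaminate_ilc && stat_count > 0 &&
        cnt - stat_count > 0.2 * cnt) {
      loc <- (loc * cnt - stat_count * stat_mean) / (cnt - stat_count)
      cnt <- cnt - stat_count
    }
    data.frame(chase_days = mg$chase_days, location = loc, count = cnt)
  }))

  ilc_pts <- ilc_pts[order(ilc_pts$chase_days), , drop = FALSE]
  sns <- comps[comps$role == "sns", ]
  sns <- sns[order(sns$chase_days), , drop = FALSE]
  ilc_traj <- fit_trajectory(ilc_pts$chase_days, ilc_pts$location)
  sns_traj <- fit_trajectory(sns$chase_days, sns$location)
  disp <- fit_dispersion(sns$chase_days, sns$dispersion)

  # exponential decay of the moving cohort (ILC + SNS movers)
  moving <- data.frame(
    chase_days = ilc_pts$chase_days,
    count = ilc_pts$count + sns$weight * sns$n_cells
  )
  decay_pts <- moving[moving$chase_days >= maturation_days, , drop = FALSE]
  decay_rate <- if (nrow(decay_pts) >= 2) {
    ols <- stats::lm(log(count) ~ chase_days, data = decay_pts)
    -unname(stats::coef(ols)[2])
  } else {
    NA_real_
  }
  life <- if (is.finite(decay_rate) && decay_rate > 0) {
    lifespan_summary(decay_rate)
  } else {
    c(half_life = NA_real_, mean_lifespan = NA_real_)
  }

  # birth ratio from timepoints where both moving components are resolved
  k4 <- comps[comps$role %in% c("ilc_moving", "sns") &
                comps$chase_days %in%
                comps$chase_days[comps$role == "ilc_moving"], ]
  birth_ratio <- if (nrow(k4) > 0) {
    by_day <- split(k4, k4$chase_days)
    mean(vapply(by_day, function(cc) {
      cc$weight[cc$role == "ilc_moving"] / cc$weight[cc$role == "sns"]
    }, numeric(1)))
  } else {
    NA_real_
  }

  structure(
    list(mixtures = fits, components = comps,
         ilc_trajectory = ilc_traj, sns_trajectory = sns_traj,
         dispersion = disp, decay_rate = decay_rate,
         half_life = unname(life["half_life"]),
         mean_lifespan = unname(life["mean_lifespan"]),
         birth_ratio = birth_ratio, moving_counts = moving,
         stationary_count = stat_count),
    class = "kinetics_recovery"
  )
}

#' @export
print.kinetics_recovery <- function(x, ...) {
  cat("Pulse-chase kinetics recovery\n")
  cat(sprintf("  ILC stream: speed %.4g radial indices/d (%s), intercept %.4g\n",
              x$ilc_trajectory$speed, x$ilc_trajectory$direction,
              x$ilc_trajectory$intercept))
  cat(sprintf("  SNS stream: speed %.4g radial indices/d (%s), intercept %.4g\n",
              x$sns_trajectory$speed, x$sns_trajectory$direction,
              x$sns_trajectory$intercept))
  cat(sprintf("  dispersion growth (SNS): %.4g sigma/d from %.4g\n",
              x$dispersion$rate, x$dispersion$baseline))
  if (is.finite(x$decay_rate)) {
    cat(sprintf("  decay rate %.4g/d -> half-life %.3g d, mean lifespan %.3g d\n",
                x$decay_rate, x$half_life, x$mean_lifespan))
  }
  if (is.finite(x$birth_ratio)) {
    cat(sprintf("  moving-cohort birth ratio ILC:SNS = %.3g\n",
                x$birth_ratio))
  }
  invisible(x)
}
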