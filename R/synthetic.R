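#' Ground-truth configuration for synthetic pulse-chase data
#'
#' Bundles the cohort-model parameters with the experiment-level quantities
#' needed to emulate a multi-timepoint thymidine-analogue pulse-chase
#' experiment: two moving cohorts born at the ILC and SNS (split by the
#' birth ratio), a minor stationary progenitor population at the ILC, a
#' stationary non-neurogenic population in the peripheral OE, chase
#' timepoints, and the sectioning layout.
#'
#' Defaults reflect the measured study conditions: stationary ILC
#' progenitors (10% of labelled cells) at 0.17 +/- 0.24, a peripheral
#' population (25%) at 1.49 +/- 0.14, 25 sections per OE, and landmark
#' lengths sns = 100 um, tip = 180 um (radial indices up to 1.8).
#'
#' @param params A `cohort_params` describing the moving cohorts.
#' @param stationary_fraction_ilc,stationary_fraction_peripheral Fractions
#'   of labelled cells in the stationary ILC-progenitor and peripheral
#'   populations (in `[0, 1]`, summing to < 1).
#' @param stationary_ilc_mean,stationary_ilc_sd Location/spread of the
#'   stationary ILC population.
#' @param peripheral_mean,peripheral_sd Location/spread of the peripheral
#'   population.
#' @param timepoints Chase days of the experiment.
#' @param sections_per_oe,oe_per_fish Sectioning layout.
#' @param sns_um,tip_um Landmark distances in micrometres.
#' @param label Label name recorded in the output table.
#' @return A `generator_truth` list.
#' @export
generator_truth <- function(params = cohort_params(),
                            stationary_fraction_ilc = 0.10,
                            stationary_fraction_peripheral = 0.25,
                            stationary_ilc_mean = 0.17,
                            stationary_ilc_sd = 0.24,
                            peripheral_mean = 1.49,
                            peripheral_sd = 0.14,
                            timepoints = c(1, 4, 21),
                            sections_per_oe = 25L,
                            oe_per_fish = 1L,
                            sns_um = 100, tip_um = 180,
                            label = "BrdU") {
  stopifnot(inherits(params, "cohort_params"),
            stationary_fraction_ilc >= 0, stationary_fraction_peripheral >= 0,
            stationary_fraction_ilc + stationary_fraction_peripheral < 1,
            length(timepoints) >= 1, all(timepoints >= 0),
            sections_per_oe >= 1, sns_um > 0, tip_um >= sns_um)
  structure(
    list(params = params,
         stationary_fraction_ilc = stationary_fraction_ilc,
         stationary_fraction_peripheral = stationary_fraction_peripheral,
         stationary_ilc_mean = stationary_ilc_mean,
         stationary_ilc_sd = stationary_ilc_sd,
         peripheral_mean = peripheral_mean,
         peripheral_sd = peripheral_sd,
         timepoints = sort(unique(timepoints)),
         sections_per_oe = as.integer(sections_per_oe),
         oe_per_fish = as.integer(oe_per_fish),
         sns_um = sns_um, tip_um = tip_um, label = label),
    class = "generator_truth"
  )
}

# draw n positions from a unit-mass component of the configured family,
# optionally truncated to [lower, upper] by rejection (matching the
# truncated cell-averaged densities of the deterministic model)
.rcomponent <- function(n, location, sd, family, mirror = FALSE,
                        lower = -Inf, upper = Inf) {
  if (n == 0) return(numeric(0))
  draw <- function(m) {
    if (family == "gaussian") return(stats::rnorm(m, location, sd))
    lp <- moment_match(location, sd)
    x <- stats::rlnorm(m, lp["mu_log"], lp["sigma_log"])
    if (mirror) 2 * location - x else x
  }
  x <- draw(n)
  for (i in seq_len(100)) {
    bad <- x < lower | x > upper
    if (!any(bad)) break
    x[bad] <- draw(sum(bad))
  }
  pmin(pmax(x, lower), upper)
}

#' Simulate a pulse-chase birthdating experiment
#'
#' For each chase timepoint, `n_cells` labelled cells are generated: each
#' cell is assigned to a population (stationary ILC progenitors, stationary
#' peripheral cells, or a moving cohort born at the ILC or SNS according to
#' the birth ratio), its birth position is drawn from that population's
#' component, moving cells drift by `speed * t` and receive independent
#' Gaussian positional noise with SD `sqrt(sigma(t)^2 - sigma0^2)` so the
#' cohort-level dispersion follows `sigma0 + dsigma * t`, and moving cells
#' survive a Bernoulli draw with probability
#' `exp(-log(2) * max(t - maturation, 0) / half_life)` (stationary
#' progenitor populations persist). Surviving cells are assigned round-robin
#' to sections and reported in micrometre and radial-index coordinates.
#'
#' The output is bit-reproducible for a fixed seed.
#'
#' @param truth A `generator_truth`.
#' @param n_cells Labelled cells per timepoint (before death).
#' @param seed Integer seed.
#' @return List with `cells` (data frame of cell observations with a
#'   `population` column carrying the generating population) and `truth`.
#' @examples
#' sim <- simulate_pulse_chase(generator_truth(), n_cells = 500, seed = 1)
#' table(sim$cells$chase_days)
#' @export
simulate_pulse_chase <- function(truth, n_cells, seed) {
  stopifnot(inherits(truth, "generator_truth"), n_cells >= 1)
  set.seed(seed)
  p <- truth$params
  br <- c(p$birth_ratio_ilc, p$birth_ratio_sns)
  br <- br / sum(br)
  move_frac <- 1 - truth$stationary_fraction_ilc -
    truth$stationary_fraction_peripheral
  probs <- c(stationary_ilc = truth$stationary_fraction_ilc,
             peripheral = truth$stationary_fraction_peripheral,
             mover_ilc = move_frac * br[1],
             mover_sns = move_frac * br[2])
  ri_max <- truth$tip_um / truth$sns_um

  per_tp <- lapply(truth$timepoints, function(t) {
    pop <- sample(names(probs), n_cells, replace = TRUE, prob = probs)
    pos <- numeric(n_cells)
    i <- pop == "stationary_ilc"
    pos[i] <- .rcomponent(sum(i), truth$stationary_ilc_mean,
                          truth$stationary_ilc_sd, p$family,
                          lower = 1e-6, upper = ri_max)
    i <- pop == "peripheral"
    pos[i] <- .rcomponent(sum(i), truth$peripheral_mean,
                          truth$peripheral_sd, p$family,
                          lower = 1e-6, upper = ri_max)
    for (stream in c("ilc", "sns")) {
      i <- pop == paste0("mover_", stream)
      if (!any(i)) next
      sigma0 <- if (stream == "ilc") p$sigma0_ilc else p$sigma0_sns
      drift <- if (stream == "ilc") p$speed_ilc * t else -p$speed_sns * t
      sig_t <- sigma0 + p$dsigma_per_day * t
      noise_sd <- sqrt(max(sig_t^2 - sigma0^2, 0))
      # positions outside the tissue are redrawn (truncation, matching the
      # cohort model's boundary convention), not clipped
      m <- sum(i)
      x <- rep(NA_real_, m)
      todo <- rep(TRUE, m)
      for (iter in 1:100) {
        nm <- sum(todo)
        if (nm == 0) break
        birth <- .rcomponent(nm, if (stream == "ilc") p$start_ilc else
          p$start_sns, sigma0, p$family,
          mirror = stream == "sns" && p$family == "lognormal" &&
            p$mirror_sns)
        cand <- birth + drift + stats::rnorm(nm, 0, noise_sd)
        x[todo] <- cand
        todo[todo] <- cand <= 0 | cand > ri_max
      }
      pos[i] <- pmin(pmax(x, 1e-6), ri_max)
    }
    surv_p <- .survival_weight(p, t, gate = FALSE)
    alive <- ifelse(startsWith(pop, "mover_"),
                    stats::runif(n_cells) < surv_p, TRUE)
    pos <- pmin(pmax(pos[alive], 0), ri_max)
    pop <- pop[alive]
    n <- length(pos)
    section <- ((seq_len(n) - 1L) %% truth$sections_per_oe) + 1L
    data.frame(
      fish_id = "sim1", oe_id = "oe1", section_index = section,
      lamella_id = "L1",
      position_um = pos * truth$sns_um,
      sns_um = truth$sns_um, tip_um = truth$tip_um,
      label = truth$label, chase_days = t,
      radial_index = pos, population = pop,
      stringsAsFactors = FALSE
    )
  })
  list(cells = do.call(rbind, per_tp), truth = truth)
}

#' Simulate a steady-state OR-expressing population
#'
#' Samples cell ages from the steady-state age distribution (uniform births,
#' exponential survival beyond maturation, truncated at the age horizon),
#' a birth stream per the birth ratio, and a position from the matching
#' cohort component. The positional histogram of a large sample converges to
#' [steady_state_profile()]; this is the stochastic agent-level counterpart
#' of the deterministic cohort sum.
#'
#' @param truth A `generator_truth` (only the embedded `cohort_params` and
#'   landmark geometry are used).
#' @param n Number of cells.
#' @param seed Integer seed.
#' @return Data frame with `age_days`, `stream` and `radial_index`.
#' @examples
#' pop <- simulate_or_population(generator_truth(), n = 2000, seed = 1)
#' hist(pop$radial_index, breaks = 50)
#' @export
simulate_or_population <- function(truth, n, seed) {
  stopifnot(inherits(truth, "generator_truth"), n >= 1)
  p <- truth$params
  if (p$maturation_days >= p$max_age_days) {
    stop("degenerate parameters: maturation_days must be below ",
         "max_age_days", call. = FALSE)
  }
  set.seed(seed)
  ages <- seq(ceiling(p$maturation_days), p$max_age_days)
  br <- c(ilc = p$birth_ratio_ilc, sns = p$birth_ratio_sns)
  br <- br / sum(br)
  grid <- default_grid()
  # joint (stream, age) weights over non-retired cohorts, mirroring the
  # deterministic cohort sum
  cells <- do.call(rbind, lapply(c("ilc", "sns"), function(s) {
    keep <- !vapply(ages, function(a) is.null(.stream_state(p, s, a, grid)),
                    logical(1))
    if (!any(keep)) return(NULL)
    data.frame(stream = s, age = ages[keep],
               weight = br[[s]] * .survival_weight(p, ages[keep],
                                                   gate = TRUE))
  }))
  if (is.null(cells) || sum(cells$weight) <= 0) {
    stop("degenerate parameters: no surviving cohorts to sample",
         call. = FALSE)
  }
  pick <- sample(nrow(cells), n, replace = TRUE, prob = cells$weight)
  age <- cells$age[pick]
  stream <- cells$stream[pick]
  ri_max <- truth$tip_um / truth$sns_um
  pos <- numeric(n)
  for (s in c("ilc", "sns")) {
    for (a in unique(age[stream == s])) {
      j <- stream == s & age == a
      st <- .stream_state(p, s, a, grid)
      pos[j] <- .rcomponent(sum(j), st$location, st$sigma, p$family,
                            st$mirror, lower = 0, upper = ri_max)
    }
  }
  data.frame(age_days = age, stream = stream,
             radial_index = pos, stringsAsFactors = FALSE)
}

#' Simulate a survival-count series
#'
#' Expected double-positive counts rise linearly from 0 at day 0 to the
#' decay curve's value at `rise_to` (the maturation rise), then follow
#' `amplitude * exp(-decay_rate * t)`. Optional multiplicative lognormal
#' noise with the given coefficient of variation (unit mean) is applied.
#'
#' @param amplitude,decay_rate Parameters of the decay curve (positive).
#' @param times Chase days.
#' @param rise_to Day at which the count maximum is reached.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @param seed Integer seed (required when `noise_cv > 0`).
#' @return Data frame with `chase_days` and `count`.
#' @examples
#' simulate_survival_counts(387.5, 0.035, times = c(4, 8, 30, 90))
#' @export
simulate_survival_counts <- function(amplitude, decay_rate, times,
                                     rise_to = 4, noise_cv = 0,
                                     seed = NULL) {
  stopifnot(amplitude > 0, decay_rate > 0, rise_to >= 0, noise_cv >= 0)
  mu <- ifelse(times < rise_to,
               (times / rise_to) * amplitude * exp(-decay_rate * rise_to),
               amplitude * exp(-decay_rate * times))
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    s2 <- log1p(noise_cv^2)
    mu <- mu * stats::rlnorm(length(mu), -s2 / 2, sqrt(s2))
  }
  data.frame(chase_days = times, count = mu)
}
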