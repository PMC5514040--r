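#' Parameters of the cohort-sum model
#'
#' The cohort-sum model generates steady-state spatial profiles of an
#' OR-expressing OSN population as the positional sum of daily birth
#' cohorts. Each cohort is born at one of the two neurogenic sites with a
#' configurable bias (`birth_ratio_ilc : birth_ratio_sns`), becomes part of
#' the OR-expressing population once it matures, drifts at constant speed
#' (centrifugally from the ILC, centripetally from the SNS), disperses
#' linearly with age, and decays exponentially with the configured
#' half-life.
#'
#' Defaults are the `"zf2017"` reference constants (see [osn_reference()]).
#'
#' @param birth_ratio_ilc,birth_ratio_sns Non-negative birth weights for the
#'   two sites (not both zero); only their ratio matters.
#' @param maturation_days Days from birth to OR expression/maturity.
#' @param half_life_days Post-maturation half-life in days.
#' @param speed_ilc,speed_sns Migration speeds in radial indices/day.
#' @param start_ilc,start_sns Birth-peak radial indices.
#' @param sigma0_ilc,sigma0_sns Initial cohort standard deviations.
#' @param dsigma_per_day Dispersion growth in sigma units/day.
#' @param max_age_days Oldest cohort included (integer days); at the default
#'   the surviving fraction is below 2%.
#' @param family Component family, `"lognormal"` (default) or `"gaussian"`.
#' @param mirror_sns Mirror the SNS-stream lognormal component about its
#'   location so its skew points centrally; a plain lognormal on the raw
#'   axis skews peripherally. Ignored for Gaussian components.
#' @return A validated `cohort_params` list.
#' @examples
#' p <- cohort_params(birth_ratio_ilc = 54.8, birth_ratio_sns = 45.2)
#' steady_state_profile(p)
#' @export
cohort_params <- function(birth_ratio_ilc = 0.5, birth_ratio_sns = 0.5,
                          maturation_days = 4, half_life_days = 19.8,
                          speed_ilc = 0.0101, speed_sns = 0.0169,
                          start_ilc = 0.0822, start_sns = 1.169,
                          sigma0_ilc = 0.0701, sigma0_sns = 0.0701,
                          dsigma_per_day = 0.0024, max_age_days = 120L,
                          family = c("lognormal", "gaussian"),
                          mirror_sns = TRUE) {
  family <- match.arg(family)
  p <- list(birth_ratio_ilc = birth_ratio_ilc,
            birth_ratio_sns = birth_ratio_sns,
            maturation_days = maturation_days,
            half_life_days = half_life_days,
            speed_ilc = speed_ilc, speed_sns = speed_sns,
            start_ilc = start_ilc, start_sns = start_sns,
            sigma0_ilc = sigma0_ilc, sigma0_sns = sigma0_sns,
            dsigma_per_day = dsigma_per_day,
            max_age_days = as.integer(max_age_days),
            family = family, mirror_sns = isTRUE(mirror_sns))
  nonneg <- c("birth_ratio_ilc", "birth_ratio_sns", "maturation_days",
              "speed_ilc", "speed_sns", "sigma0_ilc", "sigma0_sns",
              "dsigma_per_day")
  for (nm in nonneg) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0) {
      stop("`", nm, "` must be finite and >= 0", call. = FALSE)
    }
  }
  if (p$half_life_days <= 0) stop("`half_life_days` must be > 0",
                                  call. = FALSE)
  if (p$birth_ratio_ilc + p$birth_ratio_sns <= 0) {
    stop("birth weights must not both be zero", call. = FALSE)
  }
  if (p$max_age_days < p$maturation_days) {
    stop("`max_age_days` must be >= `maturation_days`", call. = FALSE)
  }
  if (p$start_ilc < 0 || p$start_sns < 0) {
    stop("birth peaks must be >= 0", call. = FALSE)
  }
  structure(p, class = "cohort_params")
}

#' @export
print.cohort_params <- function(x, ...) {
  cat(sprintf("Cohort-sum model parameters (%s components%s):\n", x$family,
              if (x$family == "lognormal" && x$mirror_sns)
                ", SNS mirrored" else ""))
  cat(sprintf("  birth ratio ILC:SNS %.3g:%.3g, maturation %g d, half-life %g d\n",
              x$birth_ratio_ilc, x$birth_ratio_sns, x$maturation_days,
              x$half_life_days))
  cat(sprintf("  ILC: start %.4g, speed %.4g/d; SNS: start %.4g, speed %.4g/d\n",
              x$start_ilc, x$speed_ilc, x$start_sns, x$speed_sns))
  cat(sprintf("  sigma0 %.4g/%.4g, dsigma %.4g/d, max age %d d\n",
              x$sigma0_ilc, x$sigma0_sns, x$dsigma_per_day, x$max_age_days))
  invisible(x)
}

#' Default radial-index grid of the model
#'
#' 361 uniformly spaced points on `[0, 1.8]` (spacing 0.005), covering the
#' sensory OE and the nonsensory periphery.
#' @return Numeric vector.
#' @export
default_grid <- function() seq(0, 1.8, length.out = 361L)

# survival weight of a cohort of the given age; gate = zero before
# maturation (OR-profile membership), otherwise decay only
.survival_weight <- function(params, age, gate = TRUE) {
  s <- exp(-log(2) * pmax(age - params$maturation_days, 0) /
             params$half_life_days)
  if (gate) s[age < params$maturation_days] <- 0
  s
}

# unit-mass component on the grid, as exact cell averages: CDF differences
# over cells centred on the grid points, truncated to the grid span and
# renormalized (cells cannot leave the tissue). The result equals the
# expected histogram of rejection-sampled positions, and its rectangle-rule
# integral is exactly 1.
.component_cdf <- function(location, sd, family, mirror = FALSE) {
  if (family == "gaussian") {
    function(q) stats::pnorm(q, location, sd)
  } else {
    lp <- moment_match(location, sd)
    if (!mirror) {
      function(q) stats::plnorm(q, lp["mu_log"], lp["sigma_log"])
    } else {
      function(q) 1 - stats::plnorm(2 * location - q,
                                    lp["mu_log"], lp["sigma_log"])
    }
  }
}

.component_pdf <- function(grid, location, sd, family, mirror = FALSE) {
  if (sd <= 0) sd <- 1e-6
  sp <- grid[2] - grid[1]
  lo <- grid[1]
  hi <- grid[length(grid)]
  edges <- pmin(pmax(c(grid - sp / 2, hi + sp / 2), lo), hi)
  cdf <- .component_cdf(location, sd, family, mirror)
  z <- cdf(hi) - cdf(lo)
  if (!is.finite(z) || z < 1e-12) return(numeric(length(grid)))
  diff(cdf(edges)) / z / sp
}

# kinematic state of a stream's cohort at a given age, or NULL when the
# cohort is retired. The centripetal (SNS) stream retires once its centre
# comes within two standard deviations of the central boundary: past that
# point the component can no longer be represented on the tissue domain
# (a mirrored lognormal with sigma >> location collapses onto single grid
# cells) and the cohort's survivors are treated as boundary deaths.
.stream_state <- function(params, stream, age, grid) {
  stream <- match.arg(stream, c("ilc", "sns"))
  floor_loc <- max(min(grid), 0) + 0.5 * (grid[2] - grid[1])
  sigma <- (if (stream == "ilc") params$sigma0_ilc else params$sigma0_sns) +
    params$dsigma_per_day * age
  if (stream == "ilc") {
    loc <- params$start_ilc + params$speed_ilc * age
    if (loc < floor_loc) loc <- floor_loc  # only reachable for exotic params
  } else {
    loc <- params$start_sns - params$speed_sns * age
    if (loc < max(floor_loc, 2 * sigma)) return(NULL)
  }
  mirror <- stream == "sns" && params$family == "lognormal" &&
    params$mirror_sns
  list(location = loc, sigma = sigma, mirror = mirror)
}

#' Spatial density of a single birth cohort
#'
#' Density on the radial-index grid of one cohort of the given age from one
#' stream: a unimodal component of the configured family located at
#' `start +/- speed * age` (centrifugal for the ILC stream, centripetal for
#' the SNS stream, clipped at the grid origin), with standard deviation
#' `sigma0 + dsigma * age`, scaled by the survival weight
#' `exp(-log(2) * max(age - maturation, 0) / half_life)`. With
#' `gate_maturation = TRUE` (the default; OR-profile convention) cohorts
#' younger than the maturation time carry zero weight, because OR expression
#' defines population membership.
#'
#' @param params A `cohort_params`.
#' @param stream `"ilc"` or `"sns"`.
#' @param age Cohort age in days (>= 0).
#' @param grid Uniform radial-index grid.
#' @param gate_maturation Zero the density for `age < maturation_days`.
#' @return Density vector over `grid`; its rectangle-rule mass equals the
#'   survival weight. A cohort whose location has passed the central
#'   boundary is retired (all-zero density, with a warning).
#' @examples
#' d <- cohort_density(cohort_params(), "ilc", age = 21)
#' sum(d) * 0.005  # surviving fraction of the cohort
#' @export
cohort_density <- function(params, stream = c("ilc", "sns"), age,
                           grid = default_grid(), gate_maturation = TRUE) {
  stopifnot(inherits(params, "cohort_params"), age >= 0)
  stream <- match.arg(stream)
  w <- .survival_weight(params, age, gate = gate_maturation)
  if (w == 0) return(numeric(length(grid)))
  st <- .stream_state(params, stream, age, grid)
  if (is.null(st)) {
    warning(sprintf("%s cohort retired at age %g: location passed the grid origin",
                    stream, age))
    return(numeric(length(grid)))
  }
  w * .component_pdf(grid, st$location, st$sigma, params$family, st$mirror)
}

.spatial_profile <- function(grid, density, normalize = TRUE) {
  spacing <- grid[2] - grid[1]
  attributes(density) <- NULL
  density[density < 0] <- 0
  mass <- sum(density) * spacing
  if (normalize) {
    if (mass <= 0) stop("degenerate parameters: profile has zero mass",
                        call. = FALSE)
    density <- density / mass
  }
  structure(
    list(grid = grid, density = density, spacing = spacing,
         normalized = normalize,
         mass_weighted_mean = sum(grid * density) * spacing /
           (sum(density) * spacing)),
    class = "spatial_profile"
  )
}

#' @export
print.spatial_profile <- function(x, ...) {
  cat(sprintf("Spatial profile: %d grid points on [%.3g, %.3g], %s, mass-weighted mean %.3f\n",
              length(x$grid), min(x$grid), max(x$grid),
              if (x$normalized) "normalized" else "unnormalized",
              x$mass_weighted_mean))
  invisible(x)
}

#' @export
plot.spatial_profile <- function(x, ...) {
  graphics::plot(x$grid, x$density, type = "l",
                 xlab = "radial index", ylab = "density", ...)
  graphics::abline(v = 1, lty = 3)
  invisible(x)
}

# per-age stream densities summed with birth-ratio weights; cohorts that
# passed the central boundary are retired (their weight is dropped here and
# accounted as boundary death by death_profile)
.sum_cohorts <- function(params, grid, age_weights) {
  br <- c(ilc = params$birth_ratio_ilc, sns = params$birth_ratio_sns)
  br <- br / sum(br)
  total <- numeric(length(grid))
  retired <- c(ilc = 0, sns = 0)
  for (i in seq_along(age_weights$age)) {
    a <- age_weights$age[i]
    w <- age_weights$weight[i]
    if (w == 0) next
    for (stream in c("ilc", "sns")) {
      if (br[[stream]] == 0) next
      st <- .stream_state(params, stream, a, grid)
      if (is.null(st)) {
        retired[[stream]] <- retired[[stream]] + w * br[[stream]]
        next
      }
      total <- total + w * br[[stream]] *
        .component_pdf(grid, st$location, st$sigma, params$family, st$mirror)
    }
  }
  if (any(retired > 0)) {
    warning(sprintf("cohorts retired at the central boundary (dropped mass: ilc %.3g, sns %.3g)",
                    retired[["ilc"]], retired[["sns"]]))
  }
  attr(total, "retired_mass") <- retired
  total
}

#' Steady-state spatial profile of an OR-expressing population
#'
#' Sums the densities of all daily cohorts from maturation to the age
#' horizon, each drifted, dispersed, and decayed according to its age and
#' weighted by the birth ratio, and normalizes the result to integrate to 1.
#' This is the model's central claim: OR-like spatial expression profiles
#' emerge from birth bias, migration, dispersion and death alone, with no
#' positional molecular cues.
#'
#' @param params A `cohort_params`.
#' @param grid Uniform radial-index grid.
#' @return A normalized `spatial_profile`.
#' @examples
#' prof <- steady_state_profile(cohort_params())
#' prof$mass_weighted_mean
#' @export
steady_state_profile <- function(params, grid = default_grid()) {
  stopifnot(inherits(params, "cohort_params"))
  ages <- seq(ceiling(params$maturation_days), params$max_age_days)
  if (length(ages) == 0) {
    stop("degenerate parameters: no mature ages in horizon", call. = FALSE)
  }
  aw <- data.frame(age = ages,
                   weight = .survival_weight(params, ages, gate = TRUE))
  .spatial_profile(grid, .sum_cohorts(params, grid, aw))
}

#' Predicted pulse-chase snapshot of a single cohort
#'
#' Density of one labelled cohort at the given chase time, per stream. This
#' links the model back to BrdU pulse-chase experiments: unlike
#' [steady_state_profile()], the snapshot is not gated on maturation
#' (labelled cells exist before they mature), so at chase 0 it returns the
#' birth-position components.
#'
#' @param params A `cohort_params`.
#' @param chase_days Days since the label pulse (>= 0).
#' @param grid Uniform radial-index grid.
#' @return List with normalized `spatial_profile`s `ilc` and `sns`.
#' @examples
#' snap <- pulse_chase_prediction(cohort_params(), 21)
#' snap$sns$grid[which.max(snap$sns$density)]  # near 0.83
#' @export
pulse_chase_prediction <- function(params, chase_days,
                                   grid = default_grid()) {
  stopifnot(inherits(params, "cohort_params"), chase_days >= 0)
  one <- function(stream) {
    d <- cohort_density(params, stream, chase_days, grid,
                        gate_maturation = FALSE)
    .spatial_profile(grid, d)
  }
  list(ilc = one("ilc"), sns = one("sns"))
}

#' Steady-state spatial profile of cell death
#'
#' Positions at which cohort cells die, at steady state: the density of each
#' cohort age weighted by the fraction of the cohort dying during that day
#' of age (`S(a) - S(a + 1)`), summed over ages and streams and normalized.
#' Because the death hazard is age-independent after maturation, deaths
#' accumulate where aged cells sit -- in the centre of the sensory OE. A
#' cohort that reaches the central boundary is retired from the population
#' profiles; its remaining survivors are booked here as deaths at the last
#' pre-boundary position, so births and deaths balance.
#'
#' The attribute `deaths_per_birth` carries the unnormalized death mass per
#' unit birth mass; it approaches 1 as the age horizon grows (conservation:
#' at steady state every born cell eventually dies).
#'
#' @param params A `cohort_params`.
#' @param grid Uniform radial-index grid.
#' @return A normalized `spatial_profile` with attribute `deaths_per_birth`.
#' @export
death_profile <- function(params, grid = default_grid()) {
  stopifnot(inherits(params, "cohort_params"))
  ages <- seq(ceiling(params$maturation_days), params$max_age_days)
  if (length(ages) == 0) {
    stop("degenerate parameters: no mature ages in horizon", call. = FALSE)
  }
  br <- c(ilc = params$birth_ratio_ilc, sns = params$birth_ratio_sns)
  br <- br / sum(br)
  total <- numeric(length(grid))
  mass <- 0
  for (stream in c("ilc", "sns")) {
    if (br[[stream]] == 0) next
    last_st <- NULL
    for (a in ages) {
      st <- .stream_state(params, stream, a, grid)
      if (is.null(st)) {
        # cohort reaches the central boundary: its remaining survivors die
        # there, at the last pre-boundary state
        if (!is.null(last_st)) {
          w <- br[[stream]] * .survival_weight(params, a, gate = FALSE)
          total <- total + w * .component_pdf(grid, last_st$location,
                                              last_st$sigma, params$family,
                                              last_st$mirror)
          mass <- mass + w
        }
        break
      }
      w <- br[[stream]] *
        (.survival_weight(params, a, gate = FALSE) -
           .survival_weight(params, a + 1, gate = FALSE))
      total <- total + w * .component_pdf(grid, st$location, st$sigma,
                                          params$family, st$mirror)
      mass <- mass + w
      last_st <- st
    }
  }
  out <- .spatial_profile(grid, total)
  attr(out, "deaths_per_birth") <- mass
  out
}

#' Similarity between two spatial profiles
#'
#' @param p,q Normalized `spatial_profile`s on identical grids.
#' @param metric `"total_variation"` (0 = identical, 1 = disjoint) or
#'   `"cosine"` (1 = identical).
#' @return Scalar in `[0, 1]`.
#' @examples
#' a <- steady_state_profile(cohort_params())
#' profile_similarity(a, a)  # 0
#' @export
profile_similarity <- function(p, q,
                               metric = c("total_variation", "cosine")) {
  metric <- match.arg(metric)
  stopifnot(inherits(p, "spatial_profile"), inherits(q, "spatial_profile"))
  if (length(p$grid) != length(q$grid) ||
      any(abs(p$grid - q$grid) > 1e-12)) {
    stop("profiles are defined on different grids", call. = FALSE)
  }
  if (metric == "total_variation") {
    0.5 * sum(abs(p$density - q$density)) * p$spacing
  } else {
    sum(p$density * q$density) /
      sqrt(sum(p$density^2) * sum(q$density^2))
  }
}

#' Empirical spatial profile from cell positions
#'
#' Bins positions into cells centred on the grid points (so the result is
#' directly comparable to model profiles on the same grid) and normalizes to
#' unit mass.
#'
#' @param positions Radial indices.
#' @param grid Uniform radial-index grid; positions outside the grid's span
#'   (plus half a spacing) are clipped to the boundary bins.
#' @return A normalized `spatial_profile`.
#' @export
profile_from_positions <- function(positions, grid = default_grid()) {
  stopifnot(length(positions) >= 1)
  spacing <- grid[2] - grid[1]
  edges <- c(grid - spacing / 2, grid[length(grid)] + spacing / 2)
  x <- pmin(pmax(positions, edges[1]), edges[length(edges)])
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = length(grid))
  .spatial_profile(grid, counts / (length(x) * spacing))
}

#' Count local modes of a spatial profile
#'
#' A grid point is a mode when it exceeds its neighbours and rises above
#' `min_height` times the profile maximum (to ignore numerical ripples).
#'
#' @param profile A `spatial_profile`.
#' @param min_height Relative height threshold.
#' @return Integer number of modes.
#' @export
profile_modes <- function(profile, min_height = 0.05) {
  d <- profile$density
  n <- length(d)
  thr <- min_height * max(d)
  is_mode <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) d[i - 1] else -Inf
    right <- if (i < n) d[i + 1] else -Inf
    d[i] > left && d[i] >= right && d[i] > thr
  }, logical(1))
  sum(is_mode)
}
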