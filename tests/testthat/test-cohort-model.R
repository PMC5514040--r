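test_that("cohort parameters are validated", {
  expect_s3_class(cohort_params(), "cohort_params")
  expect_error(cohort_params(half_life_days = 0), "half_life")
  expect_error(cohort_params(birth_ratio_ilc = 0, birth_ratio_sns = 0),
               "both be zero")
  expect_error(cohort_params(max_age_days = 2, maturation_days = 4),
               "max_age_days")
  expect_error(cohort_params(speed_ilc = -1), ">= 0")
})

test_that("cohort mass equals the survival weight exactly", {
  p <- cohort_params()
  sp <- 0.005
  # at maturation the cohort is whole
  expect_equal(sum(cohort_density(p, "ilc", p$maturation_days)) * sp, 1,
               tolerance = 1e-9)
  # one half-life after maturation, half the cohort remains
  d <- cohort_density(p, "ilc", p$maturation_days + p$half_life_days)
  expect_equal(sum(d) * sp, 0.5, tolerance = 1e-6)
  # below maturation the OR-profile weight is zero
  expect_equal(sum(cohort_density(p, "ilc", 2)), 0)
  # ungated: labelled cells exist before maturation
  expect_equal(sum(cohort_density(p, "ilc", 2, gate_maturation = FALSE)) * sp,
               1, tolerance = 1e-9)
})

test_that("cohort locations drift at the configured speeds", {
  p <- cohort_params(family = "gaussian")
  g <- default_grid()
  d <- cohort_density(p, "ilc", 21)
  expect_lt(abs(g[which.max(d)] - (0.0822 + 0.0101 * 21)), 0.006)
  d <- cohort_density(p, "sns", 21)
  expect_lt(abs(g[which.max(d)] - (1.169 - 0.0169 * 21)), 0.006)
})

test_that("steady-state profiles are normalized and shaped by birth bias", {
  prof <- suppressWarnings(steady_state_profile(cohort_params()))
  expect_equal(sum(prof$density) * prof$spacing, 1, tolerance = 1e-9)
  expect_true(all(prof$density >= 0))
  # a central-biased and a peripheral-biased receptor profile order their
  # mass-weighted means accordingly
  m_central <- suppressWarnings(steady_state_profile(
    cohort_params(birth_ratio_ilc = 54.8, birth_ratio_sns = 45.2)
  ))$mass_weighted_mean
  m_peripheral <- suppressWarnings(steady_state_profile(
    cohort_params(birth_ratio_ilc = 39.3, birth_ratio_sns = 60.7)
  ))$mass_weighted_mean
  expect_lt(m_central, m_peripheral)
  # single stationary stream collapses onto the birth component
  p0 <- cohort_params(birth_ratio_ilc = 1, birth_ratio_sns = 0,
                      speed_ilc = 0, speed_sns = 0, dsigma_per_day = 0)
  prof0 <- steady_state_profile(p0)
  birth <- cohort_density(p0, "ilc", p0$maturation_days)
  expect_equal(prof0$density, birth / (sum(birth) * prof0$spacing),
               tolerance = 1e-9)
})

test_that("the default profile is bimodal", {
  prof <- suppressWarnings(steady_state_profile(cohort_params()))
  expect_equal(profile_modes(prof), 2L)
})

test_that("longer lifespans carry cohorts further from their birth peak", {
  p <- cohort_params(birth_ratio_ilc = 1, birth_ratio_sns = 0)
  disp <- vapply(c(5, 10, 19.8, 40, 80), function(hl) {
    q <- cohort_params(birth_ratio_ilc = 1, birth_ratio_sns = 0,
                       half_life_days = hl)
    steady_state_profile(q)$mass_weighted_mean - q$start_ilc
  }, numeric(1))
  expect_true(all(diff(disp) > 0))
})

test_that("pulse-chase snapshots track the labelled cohort", {
  p <- cohort_params(family = "gaussian")
  snap0 <- pulse_chase_prediction(p, 0)
  g <- default_grid()
  expect_lt(abs(g[which.max(snap0$ilc$density)] - p$start_ilc), 0.006)
  expect_lt(abs(g[which.max(snap0$sns$density)] - p$start_sns), 0.006)
  snap21 <- pulse_chase_prediction(p, 21)
  expect_lt(abs(g[which.max(snap21$sns$density)] - 0.814), 0.01)
  expect_lt(abs(g[which.max(snap21$ilc$density)] - 0.294), 0.01)
  expect_equal(sum(snap21$sns$density) * snap21$sns$spacing, 1,
               tolerance = 1e-9)
})

test_that("death accumulates interiorly and balances birth", {
  p <- cohort_params()
  dp <- suppressWarnings(death_profile(p))
  expect_equal(sum(dp$density) * dp$spacing, 1, tolerance = 1e-9)
  mode_at <- dp$grid[which.max(dp$density)]
  expect_gt(mode_at, 0)
  expect_lt(mode_at, p$start_sns)
  # per birth, (almost) every cell dies within the age horizon
  expect_gt(attr(dp, "deaths_per_birth"), 0.97)
  expect_lte(attr(dp, "deaths_per_birth"), 1 + 1e-9)
  # with no movement, deaths happen where cells sit
  p0 <- cohort_params(speed_ilc = 0, speed_sns = 0)
  expect_lt(profile_similarity(death_profile(p0),
                               steady_state_profile(p0)), 1e-9)
})

test_that("profile similarity behaves as a metric on identical grids", {
  a <- suppressWarnings(steady_state_profile(cohort_params()))
  expect_equal(profile_similarity(a, a), 0)
  expect_equal(profile_similarity(a, a, metric = "cosine"), 1)
  lo <- profile_from_positions(runif(500, 0, 0.3))
  hi <- profile_from_positions(runif(500, 1.2, 1.6))
  expect_equal(profile_similarity(lo, hi), 1, tolerance = 1e-9)
  b <- suppressWarnings(
    steady_state_profile(cohort_params(), grid = seq(0, 1.8, length.out = 181)))
  expect_error(profile_similarity(a, b), "different grids")
})

test_that("profile sensitivity is dominated by lifespan and birth bias", {
  p <- cohort_params()
  base <- suppressWarnings(steady_state_profile(p))
  tv <- function(q) suppressWarnings(
    profile_similarity(base, steady_state_profile(q)))
  tv_hl <- max(tv(cohort_params(half_life_days = 19.8 * 1.5)),
               tv(cohort_params(half_life_days = 19.8 * 0.5)))
  tv_br <- max(tv(cohort_params(birth_ratio_ilc = 0.75,
                                birth_ratio_sns = 0.25)),
               tv(cohort_params(birth_ratio_ilc = 0.25,
                                birth_ratio_sns = 0.75)))
  tv_ds <- max(tv(cohort_params(dsigma_per_day = 0.0024 * 1.5)),
               tv(cohort_params(dsigma_per_day = 0.0024 * 0.5)))
  expect_gt(tv_hl, tv_ds)
  expect_gt(tv_br, tv_ds)
})
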