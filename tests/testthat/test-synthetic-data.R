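test_that("pulse-chase simulation is bit-reproducible under a seed", {
  tr <- generator_truth(timepoints = c(1, 4))
  a <- simulate_pulse_chase(tr, n_cells = 500, seed = 17)
  b <- simulate_pulse_chase(tr, n_cells = 500, seed = 17)
  expect_identical(a$cells, b$cells)
  c <- simulate_pulse_chase(tr, n_cells = 500, seed = 18)
  expect_false(identical(a$cells, c$cells))
})

test_that("cells are conserved across timepoints when death is disabled", {
  tr <- generator_truth(
    params = cohort_params(half_life_days = Inf),
    stationary_fraction_ilc = 0, stationary_fraction_peripheral = 0,
    timepoints = c(1, 4, 21)
  )
  sim <- simulate_pulse_chase(tr, n_cells = 2000, seed = 19)
  expect_equal(unname(table(sim$cells$chase_days)), rep(2000L, 3),
               ignore_attr = TRUE)
})

test_that("per-site birth fractions converge to the birth ratio", {
  tr <- generator_truth(
    params = cohort_params(birth_ratio_ilc = 0.6, birth_ratio_sns = 0.4),
    timepoints = 0
  )
  sim <- simulate_pulse_chase(tr, n_cells = 50000, seed = 20)
  tab <- table(sim$cells$population)
  frac_ilc <- tab[["mover_ilc"]] / (tab[["mover_ilc"]] + tab[["mover_sns"]])
  expect_lt(abs(frac_ilc - 0.6), 0.02)
  # stationary populations appear at their configured rates
  expect_lt(abs(tab[["stationary_ilc"]] / 50000 - 0.10), 0.02)
  expect_lt(abs(tab[["peripheral"]] / 50000 - 0.25), 0.02)
})

test_that("observation tables carry consistent coordinates", {
  tr <- generator_truth(timepoints = c(1, 21))
  sim <- simulate_pulse_chase(tr, n_cells = 1000, seed = 21)
  cells <- sim$cells
  expect_true(all(cells$radial_index >= 0 & cells$radial_index <= 1.8))
  expect_equal(cells$position_um, cells$radial_index * cells$sns_um,
               tolerance = 1e-12)
  expect_true(all(cells$section_index %in% 1:25))
  expect_identical(sort(unique(cells$chase_days)), c(1, 21))
})

test_that("steady-state agent sampling matches the deterministic profile", {
  tr <- generator_truth()
  pop <- simulate_or_population(tr, n = 50000, seed = 22)
  emp <- profile_from_positions(pop$radial_index)
  model <- suppressWarnings(steady_state_profile(tr$params))
  expect_lt(profile_similarity(model, emp), 0.05)
})

test_that("degenerate steady-state configurations are rejected", {
  tr <- generator_truth(params = cohort_params(maturation_days = 120,
                                               max_age_days = 120))
  expect_error(simulate_or_population(tr, 100, seed = 1), "degenerate")
  one <- generator_truth(params = cohort_params(
    birth_ratio_ilc = 1, birth_ratio_sns = 0, speed_ilc = 0
  ))
  pop <- simulate_or_population(one, 2000, seed = 2)
  expect_true(all(pop$stream == "ilc"))
  expect_lt(abs(mean(pop$radial_index) - 0.0822), 0.02)
})

test_that("survival-count series rise to maturation then decay", {
  t <- c(4, 8, 30, 90)
  sim <- simulate_survival_counts(387.5, 0.035, times = t)
  f <- fit_survival(sim$chase_days, sim$count)
  expect_equal(f$amplitude, 387.5, tolerance = 1e-7)
  expect_equal(f$decay_rate, 0.035, tolerance = 1e-9)

  sim <- simulate_survival_counts(387.5, 0.035, times = c(1, 2, 3, 4, 8),
                                  rise_to = 4)
  expect_true(all(sim$count[sim$chase_days < 4] <=
                    sim$count[sim$chase_days == 4]))
  noisy <- simulate_survival_counts(387.5, 0.035, times = c(2, 4, 8, 30, 90),
                                    noise_cv = 0.05, seed = 23)
  f <- fit_survival(noisy$chase_days, noisy$count)
  expect_lt(abs(f$decay_rate / 0.035 - 1), 0.10)
})

test_that("kinetics recovery assigns component roles sensibly", {
  tr <- generator_truth()
  sim <- simulate_pulse_chase(tr, n_cells = 6000, seed = 24)
  rec <- recover_kinetics(sim$cells, seed = 24)
  comps <- rec$components
  expect_setequal(unique(comps$role[comps$chase_days == 21]),
                  c("ilc_stationary", "ilc_moving", "sns", "peripheral"))
  expect_equal(rec$sns_trajectory$direction, "centripetal")
  expect_equal(rec$ilc_trajectory$direction, "centrifugal")
  # moderate-n sanity: estimates land in the right range
  expect_lt(abs(rec$sns_trajectory$speed / 0.0169 - 1), 0.25)
  expect_lt(abs(rec$decay_rate / 0.035 - 1), 0.30)
})
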