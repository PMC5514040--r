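test_that("radial_index normalizes to SNS or full lamella length", {
  expect_equal(radial_index(50, 100, 160), 0.5)
  expect_equal(radial_index(100, 100, 160), 1.0)
  expect_equal(radial_index(149, 100, 160), 1.49)
  expect_equal(radial_index(80, 100, 160, mode = "full"), 0.5)
  expect_equal(radial_index(160, 100, 160, mode = "full"), 1.0)
})

test_that("radial_index is monotone and round-trips through micrometres", {
  pos <- sort(runif(50, 0, 160))
  ri <- radial_index(pos, 100, 160)
  expect_true(all(diff(ri) >= 0))
  # indices -> um -> indices reproduces to machine precision
  idx <- runif(100, 0, 1.6)
  expect_equal(radial_index(idx * 100, 100, 160), idx, tolerance = 1e-12)
})

test_that("radial_index rejects invalid landmarks and positions", {
  expect_error(radial_index(10, 0, 160), "invalid landmark")
  expect_error(radial_index(10, -5, 160), "invalid landmark")
  expect_error(radial_index(10, 100, 0), "invalid landmark")
  expect_error(radial_index(10, 200, 160), "invalid landmark")
  expect_error(radial_index(170, 100, 160), "out of range")
  expect_error(radial_index(-1, 100, 160), "out of range")
})

test_that("bin_density tallies exactly and normalizes globally to unit mass", {
  h <- bin_density(rep(0.3, 10), bin_edges = c(0, 0.5, 1),
                   normalize = "global")
  expect_equal(h$counts, c(10L, 0L))
  expect_equal(h$density, c(2, 0))  # 1 over the 0.5-wide bin
  expect_equal(sum(h$density * diff(h$bin_edges)), 1, tolerance = 1e-9)

  set.seed(1)
  h <- bin_density(runif(10000), bin_edges = seq(0, 1, by = 0.1),
                   normalize = "global")
  expect_equal(sum(h$density * diff(h$bin_edges)), 1, tolerance = 1e-9)
  expect_true(all(abs(h$density - 1) < 0.15))  # law of large numbers
})

test_that("per-section normalization removes section totals", {
  # two sections with totals 100 and 300 but identical shapes
  shape <- c(0.1, 0.1, 0.5, 0.9)
  obs <- make_obs(c(rep(shape, 25), rep(shape, 75)),
                  section_index = rep(c(1L, 2L), c(100, 300)))
  h <- bin_density(obs, bin_edges = seq(0, 1, by = 0.25),
                   normalize = "per_section_total")
  single <- bin_density(make_obs(rep(shape, 25)),
                        bin_edges = seq(0, 1, by = 0.25),
                        normalize = "global")
  expect_equal(h$density, single$density, tolerance = 1e-12)
  expect_equal(h$sem, rep(0, 4), tolerance = 1e-12)
  expect_equal(h$n_sections, 2L)
  expect_equal(sum(h$density * diff(h$bin_edges)), 1, tolerance = 1e-9)
})

test_that("bin_density rejects empty and out-of-range input", {
  expect_error(bin_density(numeric(0)), "empty input")
  expect_error(bin_density(c(0.5, 2.5), bin_edges = c(0, 1, 2)),
               "outside")
  expect_error(bin_density(0.5, bin_edges = c(1, 0)), "increasing")
})

test_that("reconstruct_lamella scales each section to a 255 maximum", {
  obs <- make_obs(c(rep(0.1, 2), rep(0.4, 4)), section_index = 1L)
  hm <- reconstruct_lamella(obs, bin_edges = c(0, 0.3, 0.6, 0.9))
  expect_equal(as.numeric(hm$matrix[1, ]), c(127.5, 255, 0))

  obs <- make_obs(0.5, section_index = 3L)
  hm <- reconstruct_lamella(obs, bin_edges = c(0, 0.3, 0.6, 0.9))
  expect_equal(as.numeric(hm$matrix[1, ]), c(0, 255, 0))
})

test_that("nonempty heatmap rows peak at exactly 255", {
  set.seed(2)
  obs <- make_obs(runif(500, 0, 1.6),
                  section_index = sample(1:12, 500, replace = TRUE))
  hm <- reconstruct_lamella(obs)
  expect_true(all(apply(hm$matrix, 1, max) == 255))
  up <- reconstruct_lamella(obs, upscale = 3L)
  expect_equal(dim(up$upscaled), 3L * dim(up$matrix))
  expect_true(all(up$upscaled >= 0 & up$upscaled <= 255))
  # numeric outputs refer to the unscaled matrix
  expect_equal(up$matrix, hm$matrix)
})

test_that("pulse-day heatmap shows bands at the generator's population sites", {
  sim <- simulate_pulse_chase(generator_truth(timepoints = 1),
                              n_cells = 6000, seed = 5)
  hm <- reconstruct_lamella(sim$cells)
  mids <- (hm$bin_edges[-1] + hm$bin_edges[-length(hm$bin_edges)]) / 2
  col_mean <- colMeans(hm$matrix)
  bin_w <- diff(hm$bin_edges)[1]
  # dorso-ventral bands follow the ILC, SNS and peripheral contours
  for (target in c(0.09, 1.15, 1.49)) {
    window <- abs(mids - target) <= 0.15
    peak <- mids[window][which.max(col_mean[window])]
    expect_lt(abs(peak - target), 2 * bin_w + 1e-9)
  }
})

test_that("cell tables round-trip through CSV with derived radial index", {
  path <- withr::local_tempfile(fileext = ".csv")
  obs <- make_obs(c(0.2, 0.9, 1.3))
  write_cell_observations(obs[setdiff(names(obs), "radial_index")], path)
  back <- read_cell_observations(path)
  expect_equal(back$radial_index, obs$radial_index, tolerance = 1e-12)
})
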