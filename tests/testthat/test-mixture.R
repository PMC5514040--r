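test_that("lognormal moments and moment matching are mutual inverses", {
  expect_equal(unname(lognormal_moments(0, 0)), c(1, 0))
  expect_equal(unname(lognormal_moments(log(2), 0)), c(2, 0))
  lp <- moment_match(0.18, 0.31)
  expect_equal(unname(lognormal_moments(lp[["mu_log"]], lp[["sigma_log"]])),
               c(0.18, 0.31), tolerance = 1e-9)
  set.seed(3)
  for (i in 1:20) {
    m <- runif(1, 0.01, 5)
    s <- runif(1, 0, 2)
    lp <- moment_match(m, s)
    expect_equal(unname(lognormal_moments(lp[["mu_log"]], lp[["sigma_log"]])),
                 c(m, s), tolerance = 1e-12)
  }
  expect_error(moment_match(-1, 0.5), "positive")
  expect_error(lognormal_moments(0, -1), ">= 0")
})

test_that("single-component EM is the maximum-likelihood fixed point", {
  set.seed(4)
  x <- rnorm(60, 2, 0.5)
  f <- em_fit(x, 1, family = "gaussian")
  expect_equal(f$components$location, mean(x), tolerance = 1e-9)
  expect_equal(f$components$dispersion,
               sqrt(mean((x - mean(x))^2)), tolerance = 1e-9)
  # lognormal: exact log-space fixed point, back-transformed
  y <- rlnorm(60, 0.5, 0.3)
  f <- em_fit(y, 1, family = "lognormal")
  mom <- lognormal_moments(mean(log(y)), sqrt(mean((log(y) - mean(log(y)))^2)))
  expect_equal(f$components$location, mom[["mean"]], tolerance = 1e-9)
  expect_equal(f$components$dispersion, mom[["sd"]], tolerance = 1e-9)
})

test_that("EM recovers the three pulse-day lognormal populations", {
  set.seed(42)
  truth_mu <- c(0.18, 1.17, 1.49)
  truth_sd <- c(0.31, 0.15, 0.14)
  mix <- rmix_lognormal(30000, c(0.43, 0.32, 0.25), truth_mu, truth_sd)
  f <- em_fit(mix$x, 3, family = "lognormal", seed = 7, tol = 1e-7)
  expect_true(f$converged)
  expect_true(all(abs(f$components$location - truth_mu) < 0.02))
  # the central/ILC component has cv ~1.7; its back-transformed SD
  # estimator carries a sampling SE of ~0.015 at this n
  expect_lt(abs(f$components$dispersion[1] - truth_sd[1]), 0.04)
  expect_true(all(abs(f$components$dispersion[2:3] - truth_sd[2:3]) < 0.02))
})

test_that("EM resolves the four-population layout of a late timepoint", {
  set.seed(21)
  truth_mu <- c(0.17, 0.39, 0.82, 1.42)
  mix <- rmix_lognormal(30000, c(0.2, 0.3, 0.3, 0.2), truth_mu,
                        c(0.24, 0.19, 0.14, 0.18))
  f <- em_fit(mix$x, 4, family = "lognormal", init = "manual",
              init_locations = c(0.15, 0.4, 0.8, 1.4), seed = 7, tol = 1e-7)
  expect_equal(order(f$components$location), 1:4)
  expect_true(all(abs(f$components$location - truth_mu) < 0.06))
})

test_that("log-likelihood is non-decreasing for every family path", {
  set.seed(6)
  cases <- list(
    list(x = c(rnorm(150, 0, 1), rnorm(150, 4, 0.5)), fam = "gaussian"),
    list(x = rlnorm(300, 0, 0.8), fam = "lognormal"),
    list(x = c(rlnorm(200, -2, 0.9), rnorm(200, 1.2, 0.1)),
         fam = c("lognormal", "gaussian"))
  )
  for (cs in cases) {
    f <- em_fit(cs$x, 2, family = cs$fam, seed = 1)
    expect_true(all(diff(f$loglik_trace) > -1e-8))
  }
})

test_that("sample order does not affect the fit", {
  set.seed(7)
  x <- c(rnorm(100, 0, 1), rnorm(100, 5, 1))
  f1 <- em_fit(x, 2, family = "gaussian", init = "quantile")
  f2 <- em_fit(sample(x), 2, family = "gaussian", init = "quantile")
  expect_equal(f1$components$location, f2$components$location,
               tolerance = 1e-12)
  expect_equal(f1$components$weight, f2$components$weight,
               tolerance = 1e-12)
})

test_that("k-means initialization is deterministic under a fixed seed", {
  set.seed(8)
  x <- c(rnorm(200, 0, 1), rnorm(200, 4, 1))
  f1 <- em_fit(x, 2, family = "gaussian", init = "kmeans", seed = 11)
  f2 <- em_fit(x, 2, family = "gaussian", init = "kmeans", seed = 11)
  expect_identical(f1$components, f2$components)
  expect_identical(f1$log_likelihood, f2$log_likelihood)
})

test_that("responsibilities are proper posteriors", {
  set.seed(9)
  x <- rnorm(50, 1, 0.2)
  f1 <- em_fit(x, 1, family = "gaussian")
  expect_equal(as.numeric(responsibilities(f1, x)), rep(1, 50))

  # symmetric two-component fit: midpoint sample splits evenly
  f <- mixture_fit(c(0.5, 0.5), c(-1, 1), c(0.3, 0.3), "gaussian")
  expect_equal(as.numeric(responsibilities(f, 0)), c(0.5, 0.5),
               tolerance = 1e-9)
  # well-separated components claim their own locations
  f <- mixture_fit(c(0.5, 0.5), c(0, 6), c(1, 1), "gaussian")
  r <- responsibilities(f, c(0, 6))
  expect_gt(r[1, 1], 0.99)
  expect_gt(r[2, 2], 0.99)
  expect_equal(rowSums(r), c(1, 1), tolerance = 1e-12)
})

test_that("EM beats a dense grid search on small instances", {
  set.seed(10)
  for (case in 1:3) {
    x <- c(rnorm(100, 0, 0.7), rnorm(100, 3, 1.2))
    f <- em_fit(x, 2, family = "gaussian", init = "kmeans", seed = case)
    mus <- quantile(x, probs = seq(0.05, 0.95, length.out = 10),
                    names = FALSE)
    sds <- seq(0.3, 2, length.out = 6)
    best <- -Inf
    for (w in seq(0.1, 0.9, by = 0.1))
      for (m1 in mus) for (m2 in mus[mus > m1])
        for (s1 in sds) for (s2 in sds) {
          ll <- oracle_loglik(x, c(w, 1 - w), c(m1, m2), c(s1, s2))
          if (ll > best) best <- ll
        }
    expect_gte(f$log_likelihood, best - 1e-6)
  }
})

test_that("degenerate inputs are rejected and collapse is flagged", {
  expect_error(em_fit(rnorm(15), 2), "n >= 10")
  expect_error(em_fit(rep(1, 50), 2, family = "gaussian"), "degenerate")
  expect_error(em_fit(c(-1, rnorm(30)), 1, family = "lognormal"),
               "non-negative")
  expect_warning(
    f <- em_fit(c(rep(2, 60), rnorm(60, 8, 0.5)), 2, family = "gaussian",
                init = "manual", init_locations = c(2, 8)),
    "collapsed")
  expect_true(f$collapsed)
  # zeros under a lognormal fit are nudged, with a warning
  expect_warning(em_fit(c(0, rlnorm(40, 0, 0.3)), 1, family = "lognormal"),
                 "nudged")
})

test_that("gaussian EM agrees with an independent mixture implementation", {
  suppressMessages(library(mclust))
  set.seed(12)
  x <- c(rnorm(300, 0, 0.8), rnorm(300, 4, 1.3))
  f <- em_fit(x, 2, family = "gaussian", init = "kmeans", seed = 1,
              tol = 1e-10)
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(f$log_likelihood, mc$loglik, tolerance = 1e-4)
  expect_gte(f$log_likelihood, mc$loglik - 1e-3)
  expect_lt(max(abs(f$components$location -
                      sort(as.numeric(mc$parameters$mean)))), 0.02)
})
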