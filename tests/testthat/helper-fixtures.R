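# draw n samples from a lognormal mixture given component moments
rmix_lognormal <- function(n, weights, means, sds) {
  lp <- mapply(moment_match, means, sds)
  comp <- sample(seq_along(weights), n, replace = TRUE, prob = weights)
  list(x = stats::rlnorm(n, lp[1, comp], lp[2, comp]), comp = comp)
}

# minimal observation table at given radial indices
make_obs <- function(radial_index, section_index = 1L, label = "BrdU",
                     chase_days = 1) {
  data.frame(
    fish_id = "f1", oe_id = "oe1",
    section_index = rep_len(section_index, length(radial_index)),
    lamella_id = "L1",
    position_um = radial_index * 100, sns_um = 100, tip_um = 180,
    label = label, chase_days = chase_days,
    radial_index = radial_index
  )
}

# log-likelihood of a 1-D gaussian mixture, written independently of the
# package internals (oracle for grid-search comparisons)
oracle_loglik <- function(x, w, mu, sd) {
  dens <- sapply(seq_along(w), function(j) w[j] * dnorm(x, mu[j], sd[j]))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(x))
  sum(log(rowSums(dens)))
}
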