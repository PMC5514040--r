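Package: osndyn
Title: Population Dynamics of Adult-Born Olfactory Sensory Neurons
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of olfactory sensory neuron (OSN)
    population dynamics in the adult zebrafish olfactory epithelium from
    pulse-chase birthdating data. Converts labelled-cell positions to a
    normalized radial-index coordinate system, decomposes positional
    distributions into Gaussian or lognormal components by
    expectation-maximization, estimates migration speed, dispersion growth
    and exponential survival kinetics (half-life, mean lifespan), quantifies
    birth-site bias between the two neurogenic zones, and implements a
    cohort-sum model that generates steady-state olfactory-receptor-like
    spatial expression profiles from birth bias, maturation, drift,
    dispersion and death alone. A synthetic-data module simulates
    pulse-chase experiments with the same generative structure so every
    analysis stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    mclust,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
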