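# osndyn

Population dynamics of adult-born olfactory sensory neurons (OSNs) in the
zebrafish olfactory epithelium (OE).

In the adult zebrafish OE, new OSNs are born at two discontinuous zones --
the central interlamellar curves (ILC) and the peripheral
sensory/nonsensory border (SNS) -- switch on a single olfactory receptor
(OR) gene soon after exiting mitosis, drift radially into the sensory
tissue, and die a few weeks later. `osndyn` is a toolkit for the
quantitative side of that biology, aimed at researchers analysing
pulse-chase birthdating experiments (BrdU/IdU/CldU) or modelling receptor
expression domains:

* **Geometry** — normalized radial-index coordinates (`radial_index()`;
  ILC base = 0, SNS = 1), per-section density profiles (`bin_density()`)
  and standard-lamella heatmaps (`reconstruct_lamella()`).
* **Mixture unmixing** — EM decomposition of 1-D position distributions
  into Gaussian/lognormal components (`em_fit()`), with lognormal
  components reported as distribution mean ± SD by moment matching.
* **Kinetics** — peak-trajectory and dispersion regressions
  (`fit_trajectory()`, `fit_dispersion()`), exponential survival
  `N(t) = A e^(-λt)` (`fit_survival()`), and derived half-life
  `ln 2 / λ` and mean lifespan `1 / λ` (`lifespan_summary()`).
* **Birth bias** — quarter-segment tallies of double-positive cells
  (`segment_tally()`), ILC:SNS ratios (`bias_ratio()`) and birth-site
  attribution (`site_attribution()`).
* **Cohort-sum model** — the steady-state spatial profile of an
  OR-expressing population as the positional sum of daily cohorts that are
  born with a site bias, mature (4 d), drift (`x0 ± v·a`), disperse
  (`σ0 + Δσ·a`) and decay (`exp(-ln 2 · (a - m)/t½)`):
  `steady_state_profile()`, `pulse_chase_prediction()`,
  `death_profile()`.
* **Synthetic data** — generators with the same generative structure
  (`simulate_pulse_chase()`, `simulate_or_population()`,
  `simulate_survival_counts()`) plus a full recovery pipeline
  (`recover_kinetics()`), so every analysis stage is validated by
  parameter recovery.

## Worked example

Survival kinetics from the measured decay rate, and the migration speed of
the SNS-derived stream from its mixture peaks at chase days 1, 4 and 21:

```r
library(osndyn)

lifespan_summary(0.035)
#>     half_life mean_lifespan
#>      19.80421      28.57143

fit_trajectory(c(1, 4, 21), c(1.17, 1.07, 0.82))
#> Peak trajectory: y = -0.01655x + 1.163 (R^2: 0.980); speed 0.01655 radial indices/d, centripetal
```

So OSNs live about 19.8 d (half-life) / 28.6 d (mean), and the SNS stream
moves centripetally at ~0.017 radial indices per day — over one mean
lifespan an OSN traverses `traversal_distance(0.017, 28.6) ≈ 0.49`, about
half the sensory OE.

End-to-end parameter recovery on a synthetic pulse-chase experiment
(20,000 labelled cells per timepoint at chase days 1, 4, 21; truth:
v_ILC = 0.0101, v_SNS = 0.0169, Δσ = 0.0024/d, λ = 0.035/d, birth ratio
1.0):

```r
sim <- simulate_pulse_chase(generator_truth(), n_cells = 20000, seed = 7)
rec <- recover_kinetics(sim$cells, seed = 7)
rec
#> Pulse-chase kinetics recovery
#>   ILC stream: speed 0.009657 radial indices/d (centrifugal), intercept 0.08802
#>   SNS stream: speed 0.01728 radial indices/d (centripetal), intercept 1.172
#>   dispersion growth (SNS): 0.002383 sigma/d from 0.07187
#>   decay rate 0.03505/d -> half-life 19.8 d, mean lifespan 28.5 d
#>   moving-cohort birth ratio ILC:SNS = 0.972
```

Every generator parameter is recovered within a few percent. The
cohort-sum model closes the loop: a 50,000-agent stochastic simulation of
the same rules matches the deterministic steady-state profile to a total
variation of ~0.03, and shifting only the birth ratio moves the profile's
mass between the central and peripheral archetypes of OR expression
domains.

See the methods vignette
(`vignettes/osn-population-dynamics.Rmd`) for the model's assumptions,
parameter meanings and defaults, numerical choices, and limitations.

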