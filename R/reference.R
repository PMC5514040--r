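#' Reference parameter set for the adult zebrafish OE
#'
#' The named preset `"zf2017"` collects the measured kinetic constants for
#' adult zebrafish OSN turnover used as defaults throughout the package:
#' linear peak trajectories of the two migrating streams, dispersion growth,
#' the exponential survival curve, maturation time, daily production, the
#' per-timepoint lognormal mixture peaks of the BrdU pulse-chase series, and
#' the measured ILC/SNS birth fractions of OSN subtype markers.
#'
#' Trajectory/dispersion regression constants are stored as published
#' estimates (from a Gaussian re-fit of the mixture peaks); they are
#' intentionally not re-derived from the tabulated lognormal peaks.
#'
#' @param preset Preset name; only `"zf2017"` is defined.
#' @return A list of reference constants:
#'   \describe{
#'     \item{speed_ilc, start_ilc}{ILC stream: 0.0101 radial indices/d,
#'       intercept 0.0822 (centrifugal).}
#'     \item{speed_sns, start_sns}{SNS stream: 0.0169 radial indices/d,
#'       intercept 1.169 (centripetal).}
#'     \item{dsigma_per_day, sigma0}{Dispersion growth 0.0024 sigma/d from a
#'       baseline of 0.0701.}
#'     \item{amplitude, decay_rate}{Survival curve 387.5 e^(-0.035 t).}
#'     \item{maturation_days}{4 (peak of double-positive counts).}
#'     \item{mean_speed}{0.017 radial indices/d (average migration speed).}
#'     \item{cells_per_section, sections_per_oe}{478.8 and 25.}
#'     \item{survival_times}{Chase days of the survival series.}
#'     \item{mixture_peaks}{Data frame of lognormal component means/SDs per
#'       chase day (`population` is one of `ilc`, `ilc_moving`, `sns`,
#'       `peripheral`).}
#'     \item{birth_fractions}{Data frame of measured ILC/SNS percentages and
#'       printed ILC:SNS ratios per marker; `ompb` additionally carries the
#'       four segment fractions.}
#'     \item{ompb_segments}{Named vector of ompb segment percentages
#'       (ILC, Sc, Sp, SNS).}
#'   }
#' @examples
#' ref <- osn_reference()
#' lifespan_summary(ref$decay_rate)
#' @export
osn_reference <- function(preset = "zf2017") {
  if (!identical(preset, "zf2017")) {
    stop("unknown preset: ", preset, call. = FALSE)
  }
  mixture_peaks <- data.frame(
    chase_days = c(1, 1, 1, 4, 4, 4, 21, 21, 21, 21),
    population = c("ilc", "sns", "peripheral",
                   "ilc", "sns", "peripheral",
                   "ilc", "ilc_moving", "sns", "peripheral"),
    mean = c(0.18, 1.17, 1.49, 0.19, 1.07, 1.57, 0.17, 0.39, 0.82, 1.42),
    sd = c(0.31, 0.15, 0.14, 0.20, 0.18, 0.15, 0.24, 0.19, 0.14, 0.18)
  )
  birth_fractions <- data.frame(
    marker = c("trpc2", "v2rl1", "ompb", "or101-1", "or107-1", "or112-1"),
    pct_ilc = c(39, 53.2, 46.4 + 15.1, 39.3, 61.4, 54.8),
    pct_sns = c(61, 46.8, 29.7 + 8.8, 60.7, 38.6, 45.2),
    ratio = c(0.6, 1.1, NA, 0.6, 1.6, 1.2)
  )
  list(
    preset = "zf2017",
    speed_ilc = 0.0101, start_ilc = 0.0822,
    speed_sns = 0.0169, start_sns = 1.169,
    dsigma_per_day = 0.0024, sigma0 = 0.0701,
    amplitude = 387.5, decay_rate = 0.035,
    maturation_days = 4,
    mean_speed = 0.017,
    cells_per_section = 478.8, sections_per_oe = 25,
    survival_times = c(2, 4, 8, 30, 90),
    mixture_peaks = mixture_peaks,
    birth_fractions = birth_fractions,
    ompb_segments = c(ILC = 46.4, Sc = 15.1, Sp = 8.8, SNS = 29.7)
  )
}
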