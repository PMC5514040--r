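#' Assign sensory-OE cells to quarter segments
#'
#' The sensory OE (radial index 0 to 1) is subdivided into four equal
#' segments: ILC (interlamellar curves, `[0, 0.25)`), Sc (sensory central,
#' `[0.25, 0.5)`), Sp (sensory peripheral, `[0.5, 0.75)`) and SNS
#' (sensory/nonsensory border, `[0.75, 1]`).
#'
#' @param index Radial indices in SNS-normalized mode; must lie in
#'   `[0, 1]`. Indices above 1 are nonsensory cells and raise an error --
#'   the caller filters (or see `nonsensory` in [segment_tally()]).
#' @return Factor with levels `ILC`, `Sc`, `Sp`, `SNS`.
#' @examples
#' assign_segment(c(0.1, 0.25, 0.6, 1.0))
#' @export
assign_segment <- function(index) {
  if (any(index < 0)) stop("radial index must be >= 0", call. = FALSE)
  if (any(index > 1)) {
    stop("nonsensory cell: radial index > 1 (filter before assigning ",
         "segments)", call. = FALSE)
  }
  seg <- cut(index, breaks = c(0, 0.25, 0.5, 0.75, 1.0000001),
             labels = c("ILC", "Sc", "Sp", "SNS"), right = FALSE)
  factor(as.character(seg), levels = c("ILC", "Sc", "Sp", "SNS"))
}

#' Tally double-positive cells by sensory-OE segment
#'
#' Counts labelled cells of one marker per quarter segment and reports
#' percentage fractions with a standard error computed across sections.
#'
#' Newborn cells of the SNS stream scatter around the border itself, i.e.
#' partly at radial indices just above 1. For birth-site tallies at short
#' chase times `nonsensory = "clamp"` assigns indices in `(1, clamp_max]`
#' to the SNS segment; the default `"drop"` excludes them, and `"error"`
#' refuses them.
#'
#' @param observations Data frame with `radial_index` plus optional
#'   `fish_id`, `oe_id`, `section_index` and `label` columns, or a numeric
#'   vector of radial indices.
#' @param marker Optional marker name; when given and a `label` column is
#'   present, only matching rows are tallied.
#' @param nonsensory Handling of radial indices above 1: `"drop"`,
#'   `"clamp"`, or `"error"`.
#' @param clamp_max Upper bound for clamped indices (indices beyond it are
#'   always dropped).
#' @return A `segment_tally`: list with `marker`, `counts` (named integer
#'   vector over ILC/Sc/Sp/SNS), `fractions` (pooled percentages, summing
#'   to 100), `sem` (across sections), `n_cells`, `n_sections`, `n_oe`.
#' @examples
#' segment_tally(c(0.1, 0.12, 0.3, 0.8, 0.9))$fractions
#' @export
segment_tally <- function(observations, marker = NULL,
                          nonsensory = c("drop", "clamp", "error"),
                          clamp_max = 1.8) {
  nonsensory <- match.arg(nonsensory)
  if (is.numeric(observations)) {
    observations <- data.frame(radial_index = observations)
  }
  if (!is.null(marker) && "label" %in% names(observations)) {
    observations <- observations[observations$label == marker, , drop = FALSE]
  }
  x <- observations$radial_index
  if (nonsensory == "error" && any(x > 1)) {
    stop("nonsensory cells present (radial index > 1)", call. = FALSE)
  }
  keep <- x <= if (nonsensory == "clamp") clamp_max else 1
  observations <- observations[keep, , drop = FALSE]
  x <- pmin(observations$radial_index, 1)
  if (length(x) == 0) {
    stop("no sensory-OE cells to tally", call. = FALSE)
  }
  seg <- assign_segment(x)
  counts <- table(seg)
  fractions <- 100 * as.numeric(counts) / length(x)
  names(fractions) <- names(counts)

  key <- .section_key(observations)
  sections <- unique(key)
  sem <- if (length(sections) > 1) {
    per_sec <- t(vapply(sections, function(s) {
      tab <- table(seg[key == s])
      100 * as.numeric(tab) / sum(tab)
    }, numeric(4)))
    apply(per_sec, 2, stats::sd) / sqrt(length(sections))
  } else {
    rep(NA_real_, 4)
  }
  names(sem) <- names(counts)
  n_oe <- if (all(c("fish_id", "oe_id") %in% names(observations))) {
    length(unique(paste(observations$fish_id, observations$oe_id)))
  } else {
    1L
  }
  structure(
    list(marker = marker %||% "all", counts = counts, fractions = fractions,
         sem = sem, n_cells = length(x), n_sections = length(sections),
         n_oe = n_oe),
    class = "segment_tally"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.segment_tally <- function(x, ...) {
  cat(sprintf("Segment tally for %s (%d cells, %d sections, %d OE):\n",
              x$marker, x$n_cells, x$n_sections, x$n_oe))
  for (s in names(x$fractions)) {
    cat(sprintf("  %-3s %5.1f%%%s\n", s, x$fractions[s],
                if (is.na(x$sem[s])) "" else sprintf(" +/- %.1f", x$sem[s])))
  }
  invisible(x)
}

#' ILC:SNS birth bias ratio
#'
#' Ratio of the fraction of cells generated on the ILC side to the fraction
#' generated on the SNS side.
#'
#' @param fraction_ilc_side,fraction_sns_side Positive fractions or
#'   percentages (same units).
#' @param digits Decimal places for rounding (default 1, matching how the
#'   ratios are conventionally reported); `NULL` returns the raw ratio.
#' @return Dimensionless ratio.
#' @examples
#' bias_ratio(53.2, 46.8)  # 1.1
#' bias_ratio(39, 61)      # 0.6
#' @export
bias_ratio <- function(fraction_ilc_side, fraction_sns_side, digits = 1) {
  if (fraction_sns_side <= 0 || fraction_ilc_side <= 0) {
    stop("undefined ratio: both fractions must be positive", call. = FALSE)
  }
  r <- fraction_ilc_side / fraction_sns_side
  if (is.null(digits)) r else round(r, digits)
}

#' Attribute segment fractions to their birth site
#'
#' Cells in the two central segments are attributed to the nearer neurogenic
#' site: ILC-derived = ILC + Sc fractions, SNS-derived = SNS + Sp fractions.
#' Mid-OE cells were most plausibly generated at the nearer edge and invaded
#' the sensory OE during the chase.
#'
#' @param tally A `segment_tally`, or a numeric vector of four fractions in
#'   segment order (ILC, Sc, Sp, SNS).
#' @return Named vector `c(pct_ilc_derived, pct_sns_derived)` in the input's
#'   units (unrounded).
#' @examples
#' site_attribution(c(46.4, 15.1, 8.8, 29.7))  # ~61.5 / 38.5
#' @export
site_attribution <- function(tally) {
  f <- if (inherits(tally, "segment_tally")) tally$fractions else tally
  if (length(f) != 4) {
    stop("`tally` must provide four segment fractions", call. = FALSE)
  }
  c(pct_ilc_derived = unname(f[1] + f[2]),
    pct_sns_derived = unname(f[4] + f[3]))
}
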