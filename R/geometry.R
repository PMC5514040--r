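#' Convert a position along a lamella to the radial index
#'
#' Cell positions are measured in micrometres along a straight line from the
#' base of the interlamellar curve (ILC) towards the peripheral end of the
#' lamella. The radial index normalizes this distance either to the position
#' of the sensory/nonsensory border (`mode = "sns"`, the default; the SNS
#' maps to 1 and values greater than 1 lie in nonsensory tissue) or to the
#' entire length of the lamella (`mode = "full"`; the peripheral tip maps
#' to 1).
#'
#' @param position_um Numeric vector, distance of the cell from the ILC base
#'   in micrometres.
#' @param sns_um Position of the SNS landmark in micrometres (scalar or
#'   vector recycled against `position_um`). Must be positive.
#' @param tip_um Position of the peripheral end of the lamella in
#'   micrometres. Must be positive and at least `sns_um`.
#' @param mode `"sns"` to normalize to the SNS distance, `"full"` to
#'   normalize to the whole lamella.
#' @return Numeric vector of dimensionless radial indices.
#' @examples
#' radial_index(50, sns_um = 100, tip_um = 160)          # 0.5, mid sensory OE
#' radial_index(100, sns_um = 100, tip_um = 160)         # 1.0, at the SNS
#' radial_index(80, sns_um = 100, tip_um = 160, "full")  # 0.5 of the lamella
#' @export
radial_index <- function(position_um, sns_um, tip_um, mode = c("sns", "full")) {
  mode <- match.arg(mode)
  if (any(!is.finite(sns_um)) || any(sns_um <= 0) ||
      any(!is.finite(tip_um)) || any(tip_um <= 0)) {
    stop("invalid landmark: `sns_um` and `tip_um` must be finite and positive",
         call. = FALSE)
  }
  if (any(sns_um > tip_um)) {
    stop("invalid landmark: `sns_um` must not exceed `tip_um`", call. = FALSE)
  }
  if (any(position_um < 0) || any(position_um > tip_um)) {
    stop("position out of range: `position_um` must lie in [0, tip_um]",
         call. = FALSE)
  }
  if (mode == "sns") position_um / sns_um else position_um / tip_um
}

# section key used to group observations; missing id columns collapse to one
# section so plain numeric inputs still work
.section_key <- function(observations) {
  cols <- intersect(c("fish_id", "oe_id", "section_index"),
                    names(observations))
  if (length(cols) == 0) return(rep("s1", nrow(observations)))
  do.call(paste, c(observations[cols], sep = "/"))
}

.check_edges <- function(bin_edges) {
  if (length(bin_edges) < 2 || any(diff(bin_edges) <= 0)) {
    stop("`bin_edges` must be strictly increasing with at least two values",
         call. = FALSE)
  }
}

# half-open bins [a, b), last bin closed
.bin_index <- function(x, bin_edges) {
  if (any(x < bin_edges[1]) || any(x > bin_edges[length(bin_edges)])) {
    stop("observation outside `bin_edges` range", call. = FALSE)
  }
  findInterval(x, bin_edges, rightmost.closed = TRUE)
}

#' Bin radial positions into a density histogram
#'
#' Tallies radial indices into half-open bins (`[a, b)`, last bin closed) and
#' normalizes either globally (density integrates to 1) or per section: each
#' section's bin counts are divided by that section's total, then averaged
#' across sections with a standard error, which is how per-section frequency
#' profiles of labelled cells are reported.
#'
#' @param observations Either a numeric vector of radial indices or a data
#'   frame with a `radial_index` column plus optional `fish_id`, `oe_id`,
#'   `section_index` columns identifying sections.
#' @param bin_edges Strictly increasing bin edges covering all observations.
#'   The default covers the full radial extent `[0, 1.8]` in 50 bins.
#' @param normalize `"per_section_total"` (default), `"global"`, or `"none"`.
#' @return An object of class `density_histogram`: a list with `bin_edges`,
#'   `counts` (pooled tallies), `density`, `n_total`, `n_sections`, `sem`
#'   (per-bin standard error across sections; `NULL` unless per-section
#'   normalization is used) and `normalize`. `density` is per unit radial
#'   index, so `sum(density * diff(bin_edges))` is 1 for both normalized
#'   modes.
#' @examples
#' h <- bin_density(runif(1000), bin_edges = seq(0, 1, by = 0.1),
#'                  normalize = "global")
#' sum(h$density * diff(h$bin_edges))  # 1
#' @export
bin_density <- function(observations,
                        bin_edges = seq(0, 1.8, length.out = 51),
                        normalize = c("per_section_total", "global", "none")) {
  normalize <- match.arg(normalize)
  if (is.numeric(observations)) {
    observations <- data.frame(radial_index = observations)
  }
  if (!is.data.frame(observations) || !"radial_index" %in% names(observations)) {
    stop("`observations` must be a numeric vector or a data frame with a ",
         "`radial_index` column", call. = FALSE)
  }
  if (nrow(observations) == 0) {
    stop("empty input: at least one observation is required", call. = FALSE)
  }
  .check_edges(bin_edges)
  x <- observations$radial_index
  idx <- .bin_index(x, bin_edges)
  nbin <- length(bin_edges) - 1L
  counts <- tabulate(idx, nbins = nbin)
  width <- diff(bin_edges)
  n_total <- length(x)
  sem <- NULL
  n_sections <- 1L

  if (normalize == "global") {
    density <- counts / (n_total * width)
  } else if (normalize == "none") {
    density <- counts / width
  } else {
    key <- .section_key(observations)
    sections <- unique(key)
    n_sections <- length(sections)
    frac <- t(vapply(sections, function(s) {
      cs <- tabulate(idx[key == s], nbins = nbin)
      cs / sum(cs)
    }, numeric(nbin)))
    dens <- sweep(frac, 2, width, "/")
    density <- colMeans(dens)
    sem <- if (n_sections > 1) {
      apply(dens, 2, stats::sd) / sqrt(n_sections)
    } else {
      rep(0, nbin)
    }
  }

  structure(
    list(bin_edges = bin_edges, counts = counts, density = density,
         n_total = n_total, n_sections = n_sections, sem = sem,
         normalize = normalize),
    class = "density_histogram"
  )
}

#' @export
print.density_histogram <- function(x, ...) {
  cat("Density histogram:", length(x$counts), "bins over [",
      x$bin_edges[1], ",", x$bin_edges[length(x$bin_edges)], "],",
      x$n_total, "cells,", x$n_sections, "section(s), normalization:",
      x$normalize, "\n")
  invisible(x)
}

#' Convert a density histogram to a data frame
#'
#' @param x A `density_histogram`.
#' @param ... Unused.
#' @return Data frame with bin bounds, midpoints, counts, density and (when
#'   available) the per-bin SEM.
#' @export
as.data.frame.density_histogram <- function(x, ...) {
  nbin <- length(x$counts)
  out <- data.frame(
    bin_lo = x$bin_edges[-(nbin + 1)],
    bin_hi = x$bin_edges[-1],
    midpoint = (x$bin_edges[-1] + x$bin_edges[-(nbin + 1)]) / 2,
    count = x$counts,
    density = x$density
  )
  if (!is.null(x$sem)) out$sem <- x$sem
  out
}

# separable cubic-spline upscaling; visualization only
.upscale_matrix <- function(m, f) {
  interp1 <- function(v, xout) {
    if (length(v) < 2) return(rep(v, length(xout)))
    stats::spline(seq_along(v), v, xout = xout, method = "natural")$y
  }
  xi <- seq(1, ncol(m), length.out = ncol(m) * f)
  tmp <- t(apply(m, 1, interp1, xout = xi))
  yi <- seq(1, nrow(m), length.out = nrow(m) * f)
  out <- apply(tmp, 2, interp1, xout = yi)
  if (is.null(dim(out))) out <- matrix(out, nrow = length(yi))
  pmin(pmax(out, 0), 255)
}

#' Reconstruct a standard-lamella heatmap
#'
#' Builds the sections x bins intensity matrix used for surface-view
#' reconstructions of a standardized olfactory lamella: per section, bin
#' counts are normalized to the maximum count in that section and multiplied
#' by 255, so every section containing at least one cell has a row maximum of
#' exactly 255 and empty sections are all-zero.
#'
#' @param observations Data frame with `radial_index` and `section_index`
#'   columns (dorsal-to-ventral section order).
#' @param bin_edges Strictly increasing bin edges covering all observations.
#' @param upscale Integer >= 1. When greater than 1 an additional smoothed
#'   matrix interpolated by cubic splines (`upscale`-fold in both dimensions)
#'   is attached for visualization; all numeric summaries refer to the
#'   unscaled matrix.
#' @return An object of class `lamella_heatmap`: list with `matrix`
#'   (intensities in `[0, 255]`), `section_ids`, `bin_edges` and, when
#'   `upscale > 1`, `upscaled`.
#' @examples
#' obs <- data.frame(section_index = rep(1:2, c(6, 2)),
#'                   radial_index = c(rep(0.2, 2), rep(0.6, 4), 1.2, 1.2))
#' reconstruct_lamella(obs, bin_edges = seq(0, 1.8, by = 0.6))$matrix
#' @export
reconstruct_lamella <- function(observations,
                                bin_edges = seq(0, 1.8, length.out = 51),
                                upscale = 1L) {
  if (!is.data.frame(observations) ||
      !all(c("radial_index", "section_index") %in% names(observations))) {
    stop("`observations` must contain `radial_index` and `section_index`",
         call. = FALSE)
  }
  if (nrow(observations) == 0) {
    stop("empty input: at least one observation is required", call. = FALSE)
  }
  upscale <- as.integer(upscale)
  if (is.na(upscale) || upscale < 1) {
    stop("`upscale` must be an integer >= 1", call. = FALSE)
  }
  .check_edges(bin_edges)
  idx <- .bin_index(observations$radial_index, bin_edges)
  nbin <- length(bin_edges) - 1L
  section_ids <- sort(unique(observations$section_index))
  m <- t(vapply(section_ids, function(s) {
    cs <- tabulate(idx[observations$section_index == s], nbins = nbin)
    if (max(cs) > 0) cs / max(cs) * 255 else as.numeric(cs)
  }, numeric(nbin)))
  rownames(m) <- section_ids
  out <- list(matrix = m, section_ids = section_ids, bin_edges = bin_edges)
  if (upscale > 1) out$upscaled <- .upscale_matrix(m, upscale)
  structure(out, class = "lamella_heatmap")
}

#' @export
print.lamella_heatmap <- function(x, ...) {
  cat("Standard-lamella heatmap:", nrow(x$matrix), "sections x",
      ncol(x$matrix), "bins, intensities in [0, 255]\n")
  invisible(x)
}

#' Display a lamella heatmap
#'
#' @param x A `lamella_heatmap`.
#' @param use_upscaled Plot the interpolated matrix when available.
#' @param ... Passed to [graphics::image()].
#' @export
plot.lamella_heatmap <- function(x, use_upscaled = TRUE, ...) {
  m <- if (use_upscaled && !is.null(x$upscaled)) x$upscaled else x$matrix
  graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Inferno"),
                  xlab = "radial index (scaled bins)",
                  ylab = "section (dorsal at top)", axes = FALSE, ...)
  invisible(x)
}
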