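#' Read a table of labelled-cell observations
#'
#' Reads a delimited text file (comma or tab separated, autodetected from the
#' header line) with one row per labelled cell. Expected columns follow the
#' cell-observation schema: `fish_id`, `oe_id`, `section_index`,
#' `lamella_id`, `position_um`, `sns_um`, `tip_um`, `label`, `chase_days`
#' and optionally a precomputed `radial_index`. When `radial_index` is
#' absent it is derived with [radial_index()].
#'
#' @param path Path to a CSV/TSV file.
#' @param mode Normalization mode for the derived radial index, see
#'   [radial_index()].
#' @return Data frame of cell observations with a `radial_index` column.
#' @export
read_cell_observations <- function(path, mode = c("sns", "full")) {
  mode <- match.arg(mode)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  obs <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  required <- c("position_um", "sns_um", "tip_um")
  if (!"radial_index" %in% names(obs)) {
    if (!all(required %in% names(obs))) {
      stop("input must provide `radial_index` or the columns ",
           paste(required, collapse = ", "), call. = FALSE)
    }
    obs$radial_index <- radial_index(obs$position_um, obs$sns_um,
                                     obs$tip_um, mode = mode)
  }
  if (any(obs$radial_index < 0)) {
    stop("negative radial indices in input", call. = FALSE)
  }
  obs
}

#' Write a cell-observation table
#'
#' @param observations Data frame of cell observations.
#' @param path Output CSV path.
#' @export
write_cell_observations <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE)
  invisible(path)
}
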