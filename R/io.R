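# Tab-separated, UTF-8, '.' decimal, NA token "NA" throughout.

#' Write recorded tracks to a delimited text file
#'
#' One row per (flight, step, individual) with columns `trajectory_id`,
#' `t`, `individual_id`, `x_recorded`, `y_recorded` and, when available,
#' `x_ideal`, `y_ideal`, `offset`. Tab-separated with a header; values at
#' full precision so write/read round-trips exactly.
#'
#' @param tracks Tracks tibble (recorded positions in `x`, `y`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  out <- dplyr::rename(tracks, x_recorded = "x", y_recorded = "y")
  keep <- intersect(c("trajectory_id", "t", "individual_id",
                      "x_recorded", "y_recorded",
                      "x_ideal", "y_ideal", "offset"), names(out))
  extra <- setdiff(names(out), keep)
  out <- out[, c(keep, extra)]
  # 17 significant digits: doubles survive the text round-trip exactly
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.17g", .x)))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a trajectory table
#'
#' Reads a tab-separated trajectory file as written by [write_tracks()]
#' (or prepared externally). Requires columns `trajectory_id`, `t`,
#' `individual_id`, `x_recorded`, `y_recorded`; `x_ideal`, `y_ideal` and
#' `offset` are optional — a table with only recorded positions still
#' supports every analysis that does not need ideal positions, and a
#' notice is emitted for the ones that do. Unknown columns are preserved.
#'
#' @param path Input file path.
#' @return A tracks tibble with recorded positions in `x`, `y`.
#' @export
read_tracks <- function(path) {
  # coordinate columns come in as text and through strtod so the 17-digit
  # representation written by write_tracks() round-trips bit-exactly
  # (the stream parser is fast but inexact in the last ulp)
  numeric_cols <- c("x_recorded", "y_recorded", "x_ideal", "y_ideal",
                    "offset")
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  as_text <- intersect(numeric_cols, header)
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         progress = FALSE, na = "NA",
                         col_types = do.call(readr::cols, stats::setNames(
                           rep(list(readr::col_character()),
                               length(as_text)), as_text)))
  for (cc in intersect(numeric_cols, names(raw))) {
    raw[[cc]] <- as.numeric(raw[[cc]])
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    rlang::abort(
      paste0("Malformed rows in ", path, " (first at line ", probs$row[1],
             "): ", probs$expected[1], " vs ", probs$actual[1]),
      class = "flockdual_parse_error")
  }
  required <- c("trajectory_id", "t", "individual_id",
                "x_recorded", "y_recorded")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    rlang::abort(paste0("Missing required column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "flockdual_parse_error")
  }
  if (!all(c("x_ideal", "y_ideal") %in% names(raw))) {
    rlang::inform(
      "No ideal positions in this table; analyses that need them (e.g. regression-to-target diagnostics) are unavailable.")
  }
  dplyr::rename(raw, x = "x_recorded", y = "y_recorded")
}

#' Write a binned response map or profile as delimited text
#'
#' One row per cell with bin edges, count and mean responses; missing
#' cells carry an explicit `NA` token. Works for every map class in the
#' package (they are all tibbles of cells).
#'
#' @param map A response map / profile / delay table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  readr::write_tsv(tibble::as_tibble(map), path, na = "NA")
  invisible(path)
}
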