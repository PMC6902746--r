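#' Write a visit table as CSV
#'
#' One row per visit, comma-separated, UTF-8, header exactly
#' `participant_id, group, age, sex, apoe4, time_years, suvr, cdr_sob,
#' mmse, drs, updrs3, avlt, bnt, tmt_a, rcf`; missing scores are written
#' as empty strings.
#'
#' @param visits a visit table (e.g. `generate_cohort(cfg)$visits`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_visits <- function(visits, path) {
  missing_cols <- setdiff(VISIT_COLUMNS, names(visits))
  if (length(missing_cols)) {
    stop("visit table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- visits[, VISIT_COLUMNS, drop = FALSE]
  numeric_cols <- setdiff(VISIT_COLUMNS, c("participant_id", "group", "sex", "apoe4"))
  for (col in numeric_cols) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         formatC(out[[col]], digits = 15, format = "g"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a visit table from CSV
#'
#' Inverse of [write_visits()]: expects exactly the documented columns
#' (unknown columns are an error unless `lax = TRUE`), parses empty
#' strings as missing, and reports the first malformed row by line
#' number. The write-read round trip is lossless to full double
#' precision.
#'
#' @param path CSV file path.
#' @param lax tolerate and drop unknown columns.
#' @return A visit table data frame.
#' @export
read_visits <- function(path, lax = FALSE) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  unknown <- setdiff(names(raw), VISIT_COLUMNS)
  if (length(unknown) && !lax) {
    stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "),
         " (use lax = TRUE to drop)")
  }
  missing_cols <- setdiff(VISIT_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[, VISIT_COLUMNS, drop = FALSE]
  numeric_cols <- setdiff(VISIT_COLUMNS, c("participant_id", "group", "sex", "apoe4"))
  for (col in numeric_cols) {
    vals <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & vals != "" & is.na(parsed))
    if (length(bad)) {
      stop(sprintf("malformed value '%s' in column %s at line %d of %s",
                   vals[bad[1]], col, bad[1] + 1L, path))
    }
    raw[[col]] <- parsed
  }
  raw
}
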