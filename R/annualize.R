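#' Annualize two-visit changes in SUVR and clinical scores
#'
#' Converts a long-format visit table (baseline at time 0 plus exactly one
#' follow-up per participant) into one row per participant holding the
#' baseline value and the per-year change of SUVR and of every clinical
#' measure: `change / year = (follow-up - baseline) / interval`. A measure
#' missing at either visit yields a missing change, never 0. Because the
#' two recruitment sources have different interscan intervals (about 1.2
#' years in cases, 2.4 years in controls), annualization is what makes
#' the groups comparable.
#'
#' @param visits visit table as produced by [generate_cohort()] or read by
#'   [read_visits()]. Participants lacking a baseline or having a number
#'   of follow-ups other than one are skipped with a warning.
#' @param min_interval shortest admissible interval in years; anything
#'   shorter is an error (annualized quotients explode as the interval
#'   shrinks).
#' @return A data frame of class `amy_annualized`, one row per
#'   participant: `participant_id`, `group`, `match_block` (if present),
#'   `interval`, `baseline_suvr`, `dsuvr_per_year`, and
#'   `baseline_<measure>` / `d<measure>_per_year` for each clinical
#'   measure.
#' @export
annualize <- function(visits, min_interval = 0.25) {
  stopifnot(is.data.frame(visits))
  ids <- unique(visits$participant_id)
  rows <- vector("list", length(ids))
  skipped <- character(0)
  has_block <- "match_block" %in% names(visits)

  for (i in seq_along(ids)) {
    vv <- visits[visits$participant_id == ids[i], , drop = FALSE]
    base <- vv[vv$time_years == 0, , drop = FALSE]
    fu <- vv[vv$time_years > 0, , drop = FALSE]
    if (nrow(base) != 1L || nrow(fu) != 1L) {
      skipped <- c(skipped, ids[i])
      next
    }
    interval <- fu$time_years
    if (interval < min_interval) {
      stop(sprintf("participant %s: interval %.3f y is below the minimum %.2f y",
                   ids[i], interval, min_interval))
    }
    row <- data.frame(
      participant_id = ids[i],
      group = base$group,
      interval = interval,
      baseline_suvr = base$suvr,
      dsuvr_per_year = (fu$suvr - base$suvr) / interval,
      stringsAsFactors = FALSE
    )
    if (has_block) row$match_block <- base$match_block
    for (m in intersect(MEASURES, names(visits))) {
      row[[paste0("baseline_", m)]] <- base[[m]]
      row[[paste0("d", m, "_per_year")]] <- (fu[[m]] - base[[m]]) / interval
    }
    rows[[i]] <- row
  }
  if (length(skipped)) {
    warning("skipped ", length(skipped),
            " participant(s) without exactly one baseline and one follow-up: ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(participant_id = character(0), group = character(0),
                      interval = numeric(0), baseline_suvr = numeric(0),
                      dsuvr_per_year = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("amy_annualized", "data.frame")
  out
}
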