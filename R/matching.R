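#' Greedy nearest-age matching of controls to cases
#'
#' Builds a `ratio`:1 matched control set, matching exactly on sex and
#' APOE e4 carrier status and by nearest age within a caliper. Matching is
#' greedy and without replacement: cases are processed in ascending id
#' order; for each case the `ratio` candidates with the smallest absolute
#' age difference inside the case's sex-by-APOE stratum and within
#' `caliper` years are removed from the pool. Ties in age difference are
#' broken by ascending control id, so the procedure is deterministic and
#' seed-free.
#'
#' @param cases data frame of index cases with columns `id`, `age`, `sex`,
#'   `apoe4` (e.g. the case rows of [generate_cohort()] participants).
#' @param pool data frame of candidate controls, same columns, disjoint
#'   ids from `cases`.
#' @param ratio controls per case (default 4).
#' @param caliper maximum tolerated absolute age difference in years
#'   (default 3).
#' @param allow_partial if `TRUE`, a case with too few eligible candidates
#'   keeps the ones available (with a warning) instead of aborting.
#' @return A data frame of class `amy_matches` with one row per matched
#'   control: `case_id`, `control_id`, `age_difference` (control minus
#'   case, years), `match_block`.
#' @export
match_controls <- function(cases, pool, ratio = 4L, caliper = 3.0,
                           allow_partial = FALSE) {
  if (ratio < 1) stop("ratio must be at least 1")
  if (caliper <= 0) stop("caliper must be positive")
  for (col in c("id", "age", "sex", "apoe4")) {
    if (!col %in% names(cases) || !col %in% names(pool)) {
      stop("cases and pool must both have column '", col, "'")
    }
  }
  if (length(intersect(cases$id, pool$id))) {
    stop("pool must be disjoint from cases")
  }

  cases <- cases[order(cases$id), , drop = FALSE]
  available <- rep(TRUE, nrow(pool))
  rows <- vector("list", nrow(cases))

  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    eligible <- which(
      available &
        pool$sex == cs$sex &
        pool$apoe4 == cs$apoe4 &
        abs(pool$age - cs$age) <= caliper
    )
    if (length(eligible) < ratio) {
      msg <- sprintf(
        "case %s: only %d eligible control(s) in stratum sex=%s, apoe4=%s within %.1f y (need %d)",
        cs$id, length(eligible), cs$sex, cs$apoe4, caliper, ratio
      )
      if (!allow_partial) stop(msg)
      warning(msg)
    }
    if (length(eligible)) {
      ord <- order(abs(pool$age[eligible] - cs$age), pool$id[eligible])
      take <- eligible[ord][seq_len(min(ratio, length(eligible)))]
      available[take] <- FALSE
      rows[[i]] <- data.frame(
        case_id = cs$id,
        control_id = pool$id[take],
        age_difference = pool$age[take] - cs$age,
        match_block = cs$id,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(case_id = character(0), control_id = character(0),
                      age_difference = numeric(0), match_block = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("amy_matches", "data.frame")
  out
}

#' Restrict a cohort to matched cases and controls
#'
#' Drops unmatched pool members and stamps the `match_block` of every
#' retained participant and visit.
#'
#' @param cohort an `amy_cohort` object.
#' @param matches output of [match_controls()].
#' @return An `amy_cohort` containing only matched participants, with
#'   `match_block` filled in.
#' @export
apply_matching <- function(cohort, matches) {
  block <- c(
    stats::setNames(matches$match_block, matches$control_id),
    stats::setNames(unique(matches$match_block),
                    unique(matches$case_id))
  )
  keep <- cohort$participants$id %in% names(block)
  participants <- cohort$participants[keep, , drop = FALSE]
  participants$match_block <- unname(block[participants$id])
  visits <- cohort$visits[cohort$visits$participant_id %in% names(block), ,
                          drop = FALSE]
  rownames(participants) <- rownames(visits) <- NULL
  structure(list(participants = participants, visits = visits),
            class = "amy_cohort")
}
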