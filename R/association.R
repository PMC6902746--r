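#' Regress annualized clinical change on an amyloid predictor
#'
#' Simple (single-predictor, unadjusted) ordinary least squares of the
#' per-year change in one clinical measure on either baseline SUVR or the
#' per-year SUVR change, on complete cases only. No covariate adjustment
#' is applied by default; optional adjusters can be named.
#'
#' @param data an [annualize()] table.
#' @param outcome one of the clinical measures (`"drs"`, `"cdr_sob"`,
#'   `"mmse"`, `"updrs3"`, `"avlt"`, `"bnt"`, `"tmt_a"`, `"rcf"`); the
#'   response is its annualized change column.
#' @param predictor `"baseline_suvr"` or `"dsuvr_per_year"`.
#' @param adjust optional character vector of extra covariate columns.
#' @return A one-row data frame of class `amy_regression`: `outcome`,
#'   `predictor`, `coefficient`, `se`, `p`, `r_squared`, `n_used`.
#' @export
fit_association <- function(data, outcome, predictor = "baseline_suvr",
                            adjust = character(0)) {
  if (!predictor %in% c("baseline_suvr", "dsuvr_per_year")) {
    stop("predictor must be 'baseline_suvr' or 'dsuvr_per_year'")
  }
  ycol <- if (outcome %in% MEASURES) paste0("d", outcome, "_per_year") else outcome
  if (!ycol %in% names(data)) stop("no such outcome column: ", ycol)
  cols <- c(ycol, predictor, adjust)
  dd <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
             drop = FALSE]
  n <- nrow(dd)
  if (n < 3L) stop("fewer than 3 complete cases for outcome ", outcome)
  if (stats::var(dd[[predictor]]) == 0) {
    stop("predictor has zero variance")
  }
  fml <- stats::reformulate(c(predictor, adjust), response = ycol)
  fit <- stats::lm(fml, data = dd)
  sm <- summary(fit)
  co <- sm$coefficients[predictor, ]
  r2 <- sm$r.squared
  # a response with zero variance is fitted perfectly by the intercept
  if (stats::var(dd[[ycol]]) == 0) r2 <- 0
  out <- data.frame(
    outcome = outcome, predictor = predictor,
    coefficient = unname(co["Estimate"]), se = unname(co["Std. Error"]),
    p = unname(co["Pr(>|t|)"]), r_squared = r2, n_used = n,
    stringsAsFactors = FALSE
  )
  class(out) <- c("amy_regression", "data.frame")
  out
}

#' Full association table: every measure against both amyloid predictors
#'
#' Runs [fit_association()] for each clinical measure against baseline
#' SUVR and against annualized SUVR change — 16 unadjusted simple
#' regressions, in the conventional reporting order (all baseline-SUVR
#' rows first).
#'
#' @param data an [annualize()] table; typically restricted to the case
#'   group, where clinical decline tracks amyloid load.
#' @param outcomes measures to include (default all 8).
#' @return A data frame with one row per outcome x predictor cell.
#' @export
association_table <- function(data, outcomes = MEASURES) {
  rows <- list()
  for (pred in c("baseline_suvr", "dsuvr_per_year")) {
    for (m in outcomes) {
      rows[[paste(pred, m)]] <- fit_association(data, m, pred)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Blocked group comparison of a baseline characteristic
#'
#' Compares a baseline variable between matched cases and controls with a
#' two-way fixed-effects analysis of variance of
#' `value ~ group + match block` — the randomized-block layout induced by
#' the 4:1 matching, with the matching id as the blocking predictor.
#' Right-skewed variables can be normalized first: `"log"`,
#' `"sqrt"`, or `"sqrt_reflect"` (square root of `reflect_at - value`,
#' for ceiling-effect scores).
#'
#' @param values numeric vector, one entry per participant.
#' @param group vector of group labels, same length.
#' @param block vector of match-block identifiers, same length; every
#'   block must contain one case and at least one control.
#' @param transform `"none"` (default), `"log"`, `"sqrt"`, or
#'   `"sqrt_reflect"`.
#' @param reflect_at reflection point for `"sqrt_reflect"` (e.g. the
#'   maximum attainable score).
#' @return A list with `f_statistic`, `df1`, `df2`, `p_value`.
#' @export
compare_groups_blocked <- function(values, group, block, transform = "none",
                                   reflect_at = NULL) {
  stopifnot(length(values) == length(group), length(values) == length(block))
  keep <- !is.na(values)
  values <- values[keep]; group <- group[keep]; block <- block[keep]
  tb <- table(block, group)
  if (any(tb == 0)) {
    bad <- rownames(tb)[apply(tb == 0, 1, any)]
    stop("block(s) missing a case or all controls: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  values <- switch(transform,
    none = values,
    log = {
      if (any(values <= 0)) stop("log transform needs positive values")
      log(values)
    },
    sqrt = {
      if (any(values < 0)) stop("sqrt transform needs nonnegative values")
      sqrt(values)
    },
    sqrt_reflect = {
      if (is.null(reflect_at)) stop("sqrt_reflect needs reflect_at")
      if (any(values > reflect_at)) stop("values exceed reflect_at")
      sqrt(reflect_at - values)
    },
    stop("unknown transform: ", transform)
  )
  dd <- data.frame(value = values, group = factor(group),
                   block = factor(block))
  # a single (merged) block carries no information: plain one-way ANOVA
  fit <- if (nlevels(dd$block) > 1L) {
    stats::aov(value ~ group + block, data = dd)
  } else {
    stats::aov(value ~ group, data = dd)
  }
  tab <- summary(fit)[[1]]
  i <- grep("^group", trimws(rownames(tab)))
  res <- which(trimws(rownames(tab)) == "Residuals")
  fstat <- tab[i, "F value"]
  # degenerate layouts (no between-group information) collapse to F = 0
  ss_tot <- sum((dd$value - mean(dd$value))^2)
  scale0 <- 1e-14 * (1 + abs(mean(dd$value)))^2 * length(dd$value)
  if (is.na(fstat) || ss_tot <= scale0 || tab[i, "Sum Sq"] <= 1e-12 * ss_tot) {
    fstat <- 0
  }
  list(f_statistic = fstat, df1 = tab[i, "Df"], df2 = tab[res, "Df"],
       p_value = if (fstat == 0) 1 else tab[i, "Pr(>F)"])
}
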