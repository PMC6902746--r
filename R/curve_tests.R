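# Fixed-df natural cubic regression-spline basis used by the nested-model
# F tests: 4 df = natural cubic spline with 3 interior knots at the
# 25/50/75% quantiles of the pooled predictor. Fixing the df (instead of a
# penalty) keeps the candidate models strictly nested, so the analysis-of-
# deviance F test is exact under Gaussian errors.
fixed_df_basis <- function(x, x_all = x, df = 4L) {
  knots <- stats::quantile(x_all, probs = seq_len(df - 1L) / df, names = FALSE)
  boundary <- range(x_all)
  splines::ns(x, knots = knots, Boundary.knots = boundary)
}

check_two_groups <- function(data, min_n = 10L, min_distinct = 5L) {
  groups <- unique(data$group)
  if (length(groups) != 2L) stop("exactly two groups are required")
  for (g in groups) {
    xs <- data$baseline_suvr[data$group == g]
    if (length(xs) < min_n) {
      stop("group '", g, "' has fewer than ", min_n, " observations")
    }
    if (length(unique(xs)) < min_distinct) {
      stop("singular design: group '", g, "' has fewer than ",
           min_distinct, " distinct baseline values")
    }
  }
  groups
}

#' Test whether the rate curve differs in shape between groups
#'
#' Compares nested ordinary-least-squares models built from fixed 4-df
#' natural cubic regression splines of annualized SUVR change on baseline
#' SUVR: a single common curve for both groups versus fully group-specific
#' curves (a group-by-spline interaction). The comparison is an
#' approximate F test from the analysis-of-deviance table,
#' `F = ((RSS0 - RSS1)/ddf) / (RSS1/(n - df1))`.
#'
#' @param data an [annualize()] table (or compatible data frame) with
#'   columns `group`, `baseline_suvr`, `dsuvr_per_year`; both groups must
#'   have at least 10 observations.
#' @param df spline degrees of freedom for each group curve (default 4).
#' @return A list with `f_statistic`, `df1` (numerator df), `df2`, and
#'   `p_value`.
#' @export
test_shape_difference <- function(data, df = 4L) {
  data <- data[stats::complete.cases(
    data[, c("group", "baseline_suvr", "dsuvr_per_year")]), , drop = FALSE]
  check_two_groups(data)
  x <- data$baseline_suvr
  y <- data$dsuvr_per_year
  g <- factor(data$group)
  NS <- fixed_df_basis(x, df = df)
  m0 <- stats::lm(y ~ NS)
  m1 <- stats::lm(y ~ g * NS)
  rss0 <- sum(resid(m0)^2)
  rss1 <- sum(resid(m1)^2)
  p1 <- m1$rank
  ddf <- p1 - m0$rank
  n <- length(y)
  fstat <- max(0, (rss0 - rss1) / ddf) / (rss1 / (n - p1))
  list(f_statistic = fstat, df1 = ddf, df2 = n - p1,
       p_value = stats::pf(fstat, ddf, n - p1, lower.tail = FALSE))
}

#' Test for a vertical shift between group rate curves
#'
#' Fits a common-shape penalized spline of annualized SUVR change on
#' baseline SUVR (penalty weight tuned so the smooth carries `target_edf`
#' effective df) plus an additive group indicator, and reports the
#' indicator's estimate, standard error and two-sided p value. The
#' coefficient is in SUVR/year, with a positive sign meaning the `"case"`
#' group accumulates faster at every baseline level.
#'
#' @inheritParams test_shape_difference
#' @param target_edf effective df of the common smooth (default 4).
#' @param n_knots interior knots of the penalized basis.
#' @return A list with `coefficient`, `se`, `t`, `p_value`, `edf` (total
#'   model edf: smooth plus one for the indicator) and `lambda`.
#' @export
test_vertical_shift <- function(data, target_edf = 4, n_knots = 20L) {
  data <- data[stats::complete.cases(
    data[, c("group", "baseline_suvr", "dsuvr_per_year")]), , drop = FALSE]
  groups <- check_two_groups(data)
  if (!"case" %in% groups) {
    stop("expected a 'case' group to orient the indicator's sign")
  }
  x <- data$baseline_suvr
  y <- data$dsuvr_per_year
  g <- as.numeric(data$group == "case")
  knots <- spline_knots(x, n_knots)
  B <- spline_basis(x, knots)
  X <- cbind(B, group = g)
  K <- ncol(B)
  D <- cbind(difference_penalty(knots), 0)  # indicator column unpenalized
  # total edf target: smooth edf + 1 unpenalized df for the indicator
  lambda <- solve_lambda_for_edf(X, D, target_edf + 1)
  sol <- penalized_solve(X, y, D, lambda)
  est <- sol$coefficients[K + 1L]
  se <- sqrt(sol$cov[K + 1L, K + 1L])
  tval <- est / se
  df_resid <- length(y) - sol$edf
  list(coefficient = est, se = se, t = tval,
       p_value = 2 * stats::pt(-abs(tval), df_resid),
       edf = sol$edf, lambda = lambda)
}

#' Test the linearity of the rate-versus-baseline association
#'
#' Analysis-of-deviance F test of a straight-line OLS fit against the
#' fixed `df`-df natural cubic regression spline. A small p value means
#' the inverted-U curvature of the rate curve is real rather than noise.
#'
#' @inheritParams test_shape_difference
#' @param group `"pooled"` or a group label to filter on.
#' @return A list with `f_statistic`, `df1`, `df2`, `p_value`.
#' @export
test_linearity <- function(data, group = "pooled", df = 4L) {
  if (!identical(group, "pooled")) {
    data <- data[data$group == group, , drop = FALSE]
  }
  data <- data[stats::complete.cases(
    data[, c("baseline_suvr", "dsuvr_per_year")]), , drop = FALSE]
  x <- data$baseline_suvr
  y <- data$dsuvr_per_year
  if (length(x) < 10L) stop("need at least 10 observations")
  NS <- fixed_df_basis(x, df = df)
  m_line <- stats::lm(y ~ x)
  m_spline <- stats::lm(y ~ NS)
  ddf <- m_spline$rank - m_line$rank
  if (ddf <= 0L) {
    stop("degenerate nesting: the spline model has no more df than the line")
  }
  rss0 <- sum(resid(m_line)^2)
  rss1 <- sum(resid(m_spline)^2)
  n <- length(y)
  df2 <- n - m_spline$rank
  fstat <- max(0, (rss0 - rss1) / ddf) / (rss1 / df2)
  list(f_statistic = fstat, df1 = ddf, df2 = df2,
       p_value = stats::pf(fstat, ddf, df2, lower.tail = FALSE))
}
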