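# --- penalized B-spline machinery -------------------------------------------
#
# The rate-versus-level curve is estimated with a cubic B-spline basis on
# interior knots placed at quantiles of baseline SUVR, penalized by second
# divided differences of the coefficients evaluated at the Greville
# abscissae. The divided-difference form (rather than plain second
# differences) makes the penalty annihilate exactly the functions that are
# linear in x even with unequally spaced knots, so straight lines are never
# shrunk regardless of the penalty weight. The weight is not selected by
# GCV/REML; it is tuned by bisection so that the trace of the smoother
# matrix — the effective degrees of freedom — hits a requested value
# (4 by default).

spline_knots <- function(x, n_knots) {
  xr <- range(x)
  if (diff(xr) <= 0) stop("predictor values must not be all identical")
  # cap the basis dimension well below n so the ridge system stays
  # invertible even for a vanishing penalty weight
  n_knots <- min(n_knots, max(2L, floor(length(x) / 2) - 2L))
  probs <- seq_len(n_knots) / (n_knots + 1)
  interior <- unique(stats::quantile(x, probs, names = FALSE, type = 7))
  interior <- interior[interior > xr[1] & interior < xr[2]]
  c(rep(xr[1], 4L), interior, rep(xr[2], 4L))
}

spline_basis <- function(x, knots) {
  splines::splineDesign(knots, x, ord = 4L, outer.ok = FALSE)
}

greville <- function(knots) {
  K <- length(knots) - 4L
  vapply(seq_len(K), function(i) mean(knots[(i + 1):(i + 3)]), numeric(1))
}

# Second-order divided-difference penalty matrix: row j forms the divided
# difference c[xi_j, xi_{j+1}, xi_{j+2}], which is zero iff the coefficient
# sequence is linear in the Greville points xi.
difference_penalty <- function(knots) {
  xi <- greville(knots)
  K <- length(xi)
  if (K < 3L) stop("basis too small for a second-order penalty")
  D <- matrix(0, K - 2L, K)
  for (j in seq_len(K - 2L)) {
    d1 <- xi[j + 1] - xi[j]
    d2 <- xi[j + 2] - xi[j + 1]
    w <- 1 / (d1 + d2)
    D[j, j:(j + 2)] <- w * c(1 / d1, -(1 / d1 + 1 / d2), 1 / d2)
  }
  D
}

# All ridge algebra runs on the QR factorization of the penalty-augmented
# design [B; sqrt(lambda) D], which stays well conditioned for any lambda
# (the normal-equations route squares the condition number and loses the
# exact linear-reproduction property at extreme penalty weights).
penalized_qr <- function(B, D, lambda) {
  qra <- qr(rbind(B, sqrt(lambda) * D))
  p <- qra$pivot
  Rp <- qr.R(qra)
  # G = B[, p] R^{-1}; edf = trace of the smoother = ||G||_F^2
  G <- t(backsolve(Rp, t(B[, p, drop = FALSE]), transpose = TRUE))
  list(qra = qra, pivot = p, R = Rp, G = G, edf = sum(G^2))
}

edf_for_lambda <- function(B, D, lambda) {
  penalized_qr(B, D, lambda)$edf
}

# Bisection on log(lambda): edf is strictly decreasing in lambda, from the
# basis dimension at lambda = 0 down to the penalty null-space dimension.
solve_lambda_for_edf <- function(B, D, target_edf, tol = 0.005,
                                 max_iter = 200L) {
  lo <- 1e-12
  hi <- 1
  while (edf_for_lambda(B, D, hi) > target_edf) {
    hi <- hi * 10
    if (hi > 1e14) stop("penalty weight bisection failed to bracket the target edf")
  }
  if (edf_for_lambda(B, D, lo) < target_edf) {
    stop("target edf exceeds the basis dimension; use more knots")
  }
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    e <- edf_for_lambda(B, D, mid)
    if (abs(e - target_edf) <= tol) return(mid)
    if (e > target_edf) lo <- mid else hi <- mid
  }
  stop("penalty weight bisection did not converge in ", max_iter, " iterations")
}

penalized_solve <- function(B, y, D, lambda) {
  fac <- penalized_qr(B, D, lambda)
  coefs <- qr.coef(fac$qra, c(y, rep(0, nrow(D))))
  fitted <- drop(B %*% coefs)
  rss <- sum((y - fitted)^2)
  sigma2 <- rss / (length(y) - fac$edf)
  # sandwich covariance (B'B + lambda P)^-1 B'B (B'B + lambda P)^-1,
  # assembled in the pivoted coordinates and mapped back
  Minv <- chol2inv(fac$R)
  Bp <- B[, fac$pivot, drop = FALSE]
  covp <- sigma2 * (Minv %*% crossprod(Bp) %*% Minv)
  K <- ncol(B)
  cov <- matrix(0, K, K)
  cov[fac$pivot, fac$pivot] <- covp
  list(coefficients = unname(coefs), fitted = fitted, rss = rss,
       edf = fac$edf, sigma2 = sigma2, cov = cov)
}

#' Fit the rate-of-change versus baseline-load penalized spline
#'
#' Estimates the annualized SUVR change as a smooth function of baseline
#' SUVR with a cubic B-spline basis (interior knots at baseline-SUVR
#' quantiles) and a second-order difference penalty. Rather than selecting
#' the penalty weight automatically, the weight is tuned by bisection so
#' that the effective degrees of freedom — the trace of the smoother
#' matrix — equals `target_edf` (4 by default). Pointwise confidence
#' bands come from the sandwich covariance of the penalized estimator.
#'
#' @param data an [annualize()] table, or any data frame with columns
#'   `baseline_suvr` and `dsuvr_per_year` (and `group` if filtering).
#' @param group `"pooled"` (default) to use every row, else a group label
#'   to filter on.
#' @param target_edf requested effective degrees of freedom; must exceed 1
#'   and be below the number of observations.
#' @param n_knots number of interior knots (default 20).
#' @param lambda optional frozen penalty weight; when supplied the edf is
#'   reported as found and no bisection is performed.
#' @return An object of class `rate_curve_fit` with the knots, basis
#'   order, coefficients, penalty weight, effective df, residual variance,
#'   coefficient covariance, and the observed x-range (outside which
#'   prediction is refused).
#' @seealso [predict.rate_curve_fit()], [integrate_trajectory()]
#' @export
fit_rate_spline <- function(data, group = "pooled", target_edf = 4,
                            n_knots = 20L, lambda = NULL) {
  stopifnot(is.data.frame(data))
  if (!identical(group, "pooled")) {
    data <- data[data$group == group, , drop = FALSE]
  }
  keep <- stats::complete.cases(data[, c("baseline_suvr", "dsuvr_per_year")])
  x <- data$baseline_suvr[keep]
  y <- data$dsuvr_per_year[keep]
  n <- length(x)
  if (n < 10L) stop("need at least 10 observations to fit the rate curve")
  if (target_edf <= 1 || target_edf >= n) {
    stop("target_edf must lie strictly between 1 and the number of observations")
  }
  knots <- spline_knots(x, n_knots)
  B <- spline_basis(x, knots)
  D <- difference_penalty(knots)
  if (is.null(lambda)) {
    lambda <- solve_lambda_for_edf(B, D, target_edf)
  }
  sol <- penalized_solve(B, y, D, lambda)
  structure(
    list(group = group, knots = knots, order = 4L,
         coefficients = sol$coefficients, lambda = lambda, edf = sol$edf,
         sigma2 = sol$sigma2, cov = sol$cov, x_range = range(x), n = n,
         x = x, y = y, fitted = sol$fitted, target_edf = target_edf),
    class = "rate_curve_fit"
  )
}

#' Evaluate a fitted rate curve
#'
#' Evaluates the fitted rate (SUVR/year) at new baseline-SUVR values, with
#' optional pointwise standard errors. Extrapolation beyond the range of
#' baseline SUVR seen at fit time is refused: confidence in the curve
#' collapses where no participants were observed.
#'
#' @param object a [fit_rate_spline()] object.
#' @param x baseline SUVR values within the fitted range.
#' @param se.fit if `TRUE`, also return pointwise standard errors.
#' @param ... unused.
#' @return A numeric vector of fitted rates, or a list with `fit`, `se`,
#'   `lower`, `upper` (pointwise 95% band) when `se.fit = TRUE`.
#' @export
predict.rate_curve_fit <- function(object, x, se.fit = FALSE, ...) {
  if (any(x < object$x_range[1] - 1e-12 | x > object$x_range[2] + 1e-12)) {
    stop(sprintf("no extrapolation: x must lie within the fitted range [%.4g, %.4g]",
                 object$x_range[1], object$x_range[2]))
  }
  x <- pmin(pmax(x, object$x_range[1]), object$x_range[2])
  B <- spline_basis(x, object$knots)
  fit <- drop(B %*% object$coefficients)
  if (!se.fit) return(fit)
  se <- sqrt(pmax(rowSums((B %*% object$cov) * B), 0))
  z <- stats::qnorm(0.975)
  list(fit = fit, se = se, lower = fit - z * se, upper = fit + z * se)
}

#' Locate the peak of a fitted rate curve
#'
#' @param fit a [fit_rate_spline()] object.
#' @param grid_size number of evaluation points across the fitted range.
#' @return The baseline SUVR at which the fitted rate is largest.
#' @export
rate_curve_peak <- function(fit, grid_size = 2001L) {
  grid <- seq(fit$x_range[1], fit$x_range[2], length.out = grid_size)
  grid[which.max(predict(fit, grid))]
}

#' @export
print.rate_curve_fit <- function(x, ...) {
  cat("Penalized-spline rate curve (change in SUVR/yr vs baseline SUVR)\n")
  cat(sprintf("  group: %s, n = %d, basis dim = %d\n",
              x$group, x$n, length(x$coefficients)))
  cat(sprintf("  lambda = %.4g, effective df = %.3f (target %.2f)\n",
              x$lambda, x$edf, x$target_edf))
  cat(sprintf("  x-range: [%.3f, %.3f], residual SD = %.4g SUVR/yr\n",
              x$x_range[1], x$x_range[2], sqrt(x$sigma2)))
  invisible(x)
}

#' Serialize a rate-curve fit to JSON
#'
#' @param fit a [fit_rate_spline()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rate_fit <- function(fit, path) {
  payload <- fit[c("group", "knots", "order", "coefficients", "lambda",
                   "edf", "sigma2", "x_range", "n", "target_edf")]
  payload$cov <- fit$cov
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a rate-curve fit from JSON
#'
#' @param path a file written by [write_rate_fit()].
#' @return A `rate_curve_fit` object (without the training data).
#' @export
read_rate_fit <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$cov <- as.matrix(raw$cov)
  raw$coefficients <- as.numeric(raw$coefficients)
  raw$knots <- as.numeric(raw$knots)
  structure(raw, class = "rate_curve_fit")
}
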