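#' Bounded logistic amyloid accumulation law
#'
#' Closed-form solution of the bounded growth equation
#' \eqn{dA/dt = r (A - L)(U - A)}: the amyloid level starts at `A0` and
#' follows a sigmoid between the lower asymptote `L` (amyloid-free SUVR)
#' and the upper asymptote `U` (saturation SUVR). The instantaneous rate
#' is an inverted-U function of the current level, maximal at the midpoint
#' `(L + U) / 2`.
#'
#' Writing `x = (A - L) / (U - L)` the equation reduces to standard
#' logistic growth `dx/dt = r (U - L) x (1 - x)`, whose solution is
#' `x(t) = x0 / (x0 + (1 - x0) exp(-r (U - L) t))`.
#'
#' @param A0 starting level (SUVR), strictly inside `(L, U)`.
#' @param r growth coefficient, per (SUVR x year); `r >= 0`.
#' @param L lower asymptote (SUVR).
#' @param U upper asymptote (SUVR), `U > L`.
#' @param t time in years since the starting level; `t >= 0`. Vectorised
#'   over `t` and `A0`.
#' @return The level `A(t)` in SUVR, strictly within `(L, U)` and
#'   nondecreasing in `t`.
#' @examples
#' logistic_level(1.2, r = 0.112, L = 1.1, U = 2.5, t = 0:10)
#' @export
logistic_level <- function(A0, r, L, U, t) {
  if (!is.numeric(A0) || !is.numeric(t)) stop("A0 and t must be numeric")
  if (U <= L) stop("upper asymptote U must exceed lower asymptote L")
  if (r < 0) stop("growth coefficient r must be nonnegative")
  if (any(t < 0)) stop("time t must be nonnegative")
  if (any(A0 <= L | A0 >= U)) {
    stop("starting level A0 must lie strictly within (L, U)")
  }
  x0 <- (A0 - L) / (U - L)
  x <- x0 / (x0 + (1 - x0) * exp(-r * (U - L) * t))
  L + (U - L) * x
}

#' Instantaneous accumulation rate under the bounded logistic law
#'
#' The rate `dA/dt = r (A - L)(U - A)` at level `A`; zero outside `[L, U]`.
#'
#' @inheritParams logistic_level
#' @param A current level (SUVR).
#' @return Rate of change in SUVR per year.
#' @export
logistic_rate <- function(A, r, L, U) {
  ifelse(A <= L | A >= U, 0, r * (A - L) * (U - A))
}
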