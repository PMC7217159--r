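#' Convert a no-decay autocorrelation to its decay-model analogue
#'
#' Autocorrelations estimated under a model that assumes a flat between-period
#' correlation absorb any decay actually present in the data, so they cannot
#' be plugged directly into a decay-model calculation. Moment matching over
#' all period pairs of a T-period design equates the two models' total
#' correlation mass: the adjusted value x solves
#' \deqn{\sum_{t=1}^{T}\sum_{s=1}^{T} x^{|t-s|} = a\,T(T-1) + T,}
#' where a is the flat (no-decay) autocorrelation. Regrouping by lag, the left
#' side is \eqn{T + 2\sum_{d=1}^{T-1}(T-d)x^d}, continuous and strictly
#' increasing from T at x = 0 to \eqn{T^2} at x = 1, so a unique root in
#' `[0, 1]` always exists; it is found by bisection. Because decay
#' concentrates correlation at short lags, the adjusted (lag-1) value is
#' always at least the flat value.
#'
#' The same equation converts either the cluster autocorrelation (giving
#' \eqn{\pi_D}) or the participant autocorrelation (giving \eqn{\tau_D}).
#'
#' @param value Flat autocorrelation in `[0, 1]` estimated without decay.
#' @param periods Number of periods T (at least 2).
#' @param tol Absolute bisection tolerance on the root.
#' @return The per-period decay parameter in `[0, 1]`.
#' @examples
#' adjust_autocorrelation(0.7, periods = 4) # ~0.80
#' adjust_autocorrelation(0.9, periods = 4) # ~0.94
#' @export
adjust_autocorrelation <- function(value, periods, tol = 1e-10) {
  stopifnot(value >= 0, value <= 1, periods >= 2)
  if (value == 0) return(0)
  if (value == 1) return(1)
  target <- value * periods * (periods - 1) + periods
  f <- function(x) .lag_weighted_sum(x, periods) - target
  lo <- 0
  hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# T + 2 * sum_{d=1}^{T-1} (T - d) x^d : the double sum over |t - s| regrouped
# by lag.
.lag_weighted_sum <- function(x, periods) {
  d <- seq_len(periods - 1)
  periods + 2 * sum((periods - d) * x^d)
}

#' Flat autocorrelation implied by a decay parameter
#'
#' Inverse of [adjust_autocorrelation()]: the flat (no-decay) autocorrelation
#' whose total correlation mass over a T-period design matches a geometric
#' decay with per-period parameter `value`,
#' \deqn{a = \frac{2\sum_{d=1}^{T-1}(T-d)\,x^d}{T(T-1)}.}
#'
#' @param value Per-period decay parameter in `[0, 1]`.
#' @param periods Number of periods T (at least 2).
#' @return Flat autocorrelation in `[0, 1]`.
#' @export
implied_flat_autocorrelation <- function(value, periods) {
  stopifnot(value >= 0, value <= 1, periods >= 2)
  d <- seq_len(periods - 1)
  2 * sum((periods - d) * value^d) / (periods * (periods - 1))
}
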