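#' Variance components for the block-exchangeable outcome model
#'
#' Parameterizes the individual-level model
#' \deqn{Y_{kti} = \beta_t + \theta X_{kt} + C_k + CP_{kt} + \eta_{ki} + \epsilon_{kti}}
#' with cluster effects \eqn{C_k \sim N(0, \sigma_C^2)}, cluster-period effects
#' \eqn{CP_{kt} \sim N(0, \sigma_{CP}^2)}, participant effects
#' \eqn{\eta_{ki} \sim N(0, \sigma_\eta^2)} and residuals
#' \eqn{\epsilon_{kti} \sim N(0, \sigma_\epsilon^2)}, through the correlation
#' parameters a trialist usually has:
#' total variance \eqn{\sigma^2}, intracluster correlation
#' \eqn{\rho = (\sigma_C^2 + \sigma_{CP}^2)/\sigma^2}, cluster autocorrelation
#' \eqn{\pi = \sigma_C^2/(\sigma_C^2 + \sigma_{CP}^2)} and participant
#' autocorrelation \eqn{\tau = \sigma_\eta^2/(\sigma_\eta^2 + \sigma_\epsilon^2)}.
#'
#' The implied components are \eqn{\sigma_C^2 = \sigma^2\rho\pi},
#' \eqn{\sigma_{CP}^2 = \sigma^2\rho(1-\pi)},
#' \eqn{\sigma_\eta^2 = \sigma^2(1-\rho)\tau} and
#' \eqn{\sigma_\epsilon^2 = \sigma^2(1-\rho)(1-\tau)}; they are nonnegative and
#' sum to \eqn{\sigma^2} by construction.
#'
#' When `rho = 0` the cluster autocorrelation is undefined as a ratio and is
#' treated as 0 (`pi` may then be omitted); the component decomposition is
#' unaffected.
#'
#' @param sigma2 Total outcome variance (> 0), in squared outcome units.
#' @param rho Intracluster correlation, in `[0, 1)`.
#' @param pi Cluster autocorrelation, in `[0, 1]`. Ignored (treated as 0) when
#'   `rho = 0`.
#' @param tau Participant autocorrelation, in `[0, 1]`.
#'
#' @return An object of class `vc_block_exchangeable`: a list with the four
#'   correlation parameters and the derived components `sigma_C2`,
#'   `sigma_CP2`, `sigma_eta2`, `sigma_eps2`.
#' @seealso [decay_components()] for the discrete-time decay model.
#' @examples
#' variance_components(sigma2 = 25, rho = 0.33, pi = 0.9, tau = 0.7)
#' @export
variance_components <- function(sigma2, rho, pi = NULL, tau) {
  stopifnot(is.numeric(sigma2), length(sigma2) == 1L, sigma2 > 0)
  stopifnot(is.numeric(rho), length(rho) == 1L, rho >= 0, rho < 1)
  if (rho == 0) {
    pi <- 0
  } else if (is.null(pi)) {
    stop("pi must be supplied when rho > 0", call. = FALSE)
  }
  stopifnot(is.numeric(pi), length(pi) == 1L, pi >= 0, pi <= 1)
  stopifnot(is.numeric(tau), length(tau) == 1L, tau >= 0, tau <= 1)
  structure(
    list(sigma2 = sigma2, rho = rho, pi = pi, tau = tau,
         sigma_C2   = sigma2 * rho * pi,
         sigma_CP2  = sigma2 * rho * (1 - pi),
         sigma_eta2 = sigma2 * (1 - rho) * tau,
         sigma_eps2 = sigma2 * (1 - rho) * (1 - tau)),
    class = "vc_block_exchangeable"
  )
}

#' Variance components for the discrete-time decay model
#'
#' Parameterizes the outcome model
#' \deqn{Y_{kti} = \beta_t + \theta X_{kt} + CP_{kt} + \epsilon_{kti}}
#' in which cluster-period effects are correlated over time with
#' \eqn{\mathrm{cor}(CP_{kt}, CP_{ks}) = \pi_D^{|t-s|}} and a participant's
#' errors are autoregressive with \eqn{\mathrm{cor}(\epsilon_{kti},
#' \epsilon_{ksi}) = \tau_D^{|t-s|}}. Inputs are the total variance
#' \eqn{\sigma_D^2 = \sigma_{CP,D}^2 + \sigma_{\epsilon D}^2} and the
#' within-period intracluster correlation
#' \eqn{\rho_D = \sigma_{CP,D}^2 / \sigma_D^2}.
#'
#' `pi_D` and `tau_D` are per-period decays: the correlation lost per period of
#' separation, not a flat between-period correlation. Autocorrelations
#' estimated under a model without decay should be converted first with
#' [adjust_autocorrelation()].
#'
#' With `pi_D = 1` and `tau_D = 1` this model coincides with the
#' block-exchangeable model having `pi = 1`, `tau = 1` and matched components.
#'
#' @param sigma2 Total outcome variance \eqn{\sigma_D^2} (> 0).
#' @param rho Intracluster correlation \eqn{\rho_D}, in `[0, 1)`.
#' @param pi_D Per-period decay of the cluster-period correlation, in `[0, 1]`.
#' @param tau_D Per-period decay of the within-participant correlation, in
#'   `[0, 1]`.
#' @return An object of class `vc_decay`: a list with the inputs and the
#'   derived components `sigma_CP2` and `sigma_eps2`.
#' @examples
#' decay_components(sigma2 = 25, rho = 0.33, pi_D = 0.94, tau_D = 0.80)
#' @export
decay_components <- function(sigma2, rho, pi_D, tau_D) {
  stopifnot(is.numeric(sigma2), length(sigma2) == 1L, sigma2 > 0)
  stopifnot(is.numeric(rho), length(rho) == 1L, rho >= 0, rho < 1)
  stopifnot(is.numeric(pi_D), length(pi_D) == 1L, pi_D >= 0, pi_D <= 1)
  stopifnot(is.numeric(tau_D), length(tau_D) == 1L, tau_D >= 0, tau_D <= 1)
  structure(
    list(sigma2 = sigma2, rho = rho, pi_D = pi_D, tau_D = tau_D,
         sigma_CP2  = sigma2 * rho,
         sigma_eps2 = sigma2 * (1 - rho)),
    class = "vc_decay"
  )
}

#' @export
print.vc_block_exchangeable <- function(x, ...) {
  cat("Block-exchangeable variance components\n")
  cat(sprintf("  sigma2 = %g, rho = %g, pi = %g, tau = %g\n",
              x$sigma2, x$rho, x$pi, x$tau))
  cat(sprintf("  sigma_C2 = %g, sigma_CP2 = %g, sigma_eta2 = %g, sigma_eps2 = %g\n",
              x$sigma_C2, x$sigma_CP2, x$sigma_eta2, x$sigma_eps2))
  invisible(x)
}

#' @export
print.vc_decay <- function(x, ...) {
  cat("Discrete-time decay variance components\n")
  cat(sprintf("  sigma2 = %g, rho = %g, pi_D = %g, tau_D = %g\n",
              x$sigma2, x$rho, x$pi_D, x$tau_D))
  cat(sprintf("  sigma_CP2 = %g, sigma_eps2 = %g\n", x$sigma_CP2, x$sigma_eps2))
  invisible(x)
}
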