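#' Covariance of cluster-period means, block-exchangeable model
#'
#' Builds the T x T covariance matrix of a cluster's vector of cluster-period
#' means under the block-exchangeable model. Collapsing the individual-level
#' model to means gives
#' \deqn{\mathrm{var}(\bar Y_{kt}) = \sigma_C^2 + \sigma_{CP}^2 +
#'   (\sigma_\eta^2 + \sigma_\epsilon^2)/m}
#' \deqn{\mathrm{cov}(\bar Y_{kt}, \bar Y_{ks}) = \sigma_C^2 +
#'   \sigma_\eta^2 (1 - \chi(t,s))/m,}
#' so only the cluster effect and the retained fraction of participant effects
#' carry over between periods. For Beta-distributed churn the expectation
#' \eqn{E[\chi_k]} enters, which is exactly what the covariance depends on.
#'
#' @param vc A [variance_components()] object.
#' @param scheme A [sampling_scheme()].
#' @param m Cluster-period size.
#' @param T Number of periods.
#' @return Symmetric positive semidefinite T x T matrix.
#' @export
cov_matrix_block_exchangeable <- function(vc, scheme, m, T) {
  stopifnot(inherits(vc, "vc_block_exchangeable"))
  chi <- churn_matrix(scheme, T, m)
  V <- vc$sigma_C2 + vc$sigma_eta2 * (1 - chi) / m
  diag(V) <- vc$sigma_C2 + vc$sigma_CP2 + (vc$sigma_eta2 + vc$sigma_eps2) / m
  .check_psd(V, scheme)
  V
}

#' Covariance of cluster-period means, discrete-time decay model
#'
#' Builds the T x T covariance matrix of cluster-period means under the decay
#' model: cluster-period effects decay geometrically with lag
#' (\eqn{\pi_D^{|t-s|}}) and a retained participant's errors decay as
#' \eqn{\tau_D^{|t-s|}}, the participant term being further weighted by the
#' retention rate:
#' \deqn{\mathrm{cov}(\bar Y_{kt}, \bar Y_{ks}) =
#'   \sigma_{CP,D}^2 \pi_D^{|t-s|} +
#'   \frac{\sigma_{\epsilon D}^2}{m} \tau_D^{|t-s|} (1 - \chi(t,s)),}
#' with diagonal \eqn{\sigma_{CP,D}^2 + \sigma_{\epsilon D}^2/m}. Under
#' in-for-p rotation sampling the retention factor is
#' \eqn{(1 - |t-s|/p)} for lags up to p and 0 beyond, so the participant term
#' vanishes for pairs more than p periods apart.
#'
#' @param vc A [decay_components()] object.
#' @inheritParams cov_matrix_block_exchangeable
#' @return Symmetric positive semidefinite T x T matrix.
#' @export
cov_matrix_decay <- function(vc, scheme, m, T) {
  stopifnot(inherits(vc, "vc_decay"))
  chi <- churn_matrix(scheme, T, m)
  lag <- abs(outer(seq_len(T), seq_len(T), "-"))
  V <- vc$sigma_CP2 * vc$pi_D^lag +
    (vc$sigma_eps2 / m) * vc$tau_D^lag * (1 - chi)
  diag(V) <- vc$sigma_CP2 + vc$sigma_eps2 / m
  .check_psd(V, scheme)
  V
}

#' Covariance of cluster-period means for either correlation model
#'
#' Dispatches to [cov_matrix_block_exchangeable()] or [cov_matrix_decay()]
#' according to the class of `vc`.
#'
#' @param vc A [variance_components()] or [decay_components()] object.
#' @inheritParams cov_matrix_block_exchangeable
#' @return Symmetric positive semidefinite T x T matrix.
#' @export
cov_cluster_period_means <- function(vc, scheme, m, T) {
  if (inherits(vc, "vc_block_exchangeable")) {
    cov_matrix_block_exchangeable(vc, scheme, m, T)
  } else if (inherits(vc, "vc_decay")) {
    cov_matrix_decay(vc, scheme, m, T)
  } else {
    stop("vc must be a variance_components() or decay_components() object",
         call. = FALSE)
  }
}

# A churn table that is not realizable by any membership process can produce
# an indefinite matrix; only custom tables can get here.
.check_psd <- function(V, scheme) {
  ev <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-10 * max(diag(V))) {
    stop(sprintf(
      "invalid-scheme: %s churn specification yields a non positive semidefinite covariance (min eigenvalue %.3g)",
      scheme$kind, ev), call. = FALSE)
  }
  invisible(V)
}
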