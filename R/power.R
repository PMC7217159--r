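#' Correlation between two cluster-period means under constant churn
#'
#' For the block-exchangeable model with a churn rate that is constant across
#' period pairs, the correlation between any two cluster-period means from the
#' same cluster is
#' \deqn{r = \frac{m\rho\pi + (1-\rho)\tau(1-\chi)}{1 + (m-1)\rho},}
#' equivalently the ratio of the between-period covariance
#' \eqn{\sigma_C^2 + \sigma_\eta^2(1-\chi)/m} to the cluster-period-mean
#' variance \eqn{\sigma_C^2 + \sigma_{CP}^2 + (\sigma_\eta^2 +
#' \sigma_\epsilon^2)/m}. At `chi = 1` it reduces to the repeated
#' cross-section value \eqn{m\rho\pi/(1+(m-1)\rho)} and at `chi = 0` to the
#' closed-cohort value \eqn{(m\rho\pi + (1-\rho)\tau)/(1+(m-1)\rho)}: churn
#' simply multiplies the participant autocorrelation by the retention rate.
#'
#' @param vc A [variance_components()] object.
#' @param m Cluster-period size.
#' @param chi Constant churn rate in `[0, 1]`.
#' @return Correlation r in `[0, 1]`.
#' @export
compute_r <- function(vc, m, chi) {
  stopifnot(inherits(vc, "vc_block_exchangeable"),
            chi >= 0, chi <= 1, m >= 1)
  (m * vc$rho * vc$pi + (1 - vc$rho) * vc$tau * (1 - chi)) /
    (1 + (m - 1) * vc$rho)
}

#' Longitudinal design effect
#'
#' The design effect accounting for repeated measurement of clusters over
#' time. With each cluster on its own row of the expanded treatment matrix
#' (K rows, T periods), grand total \eqn{X_{\bullet\bullet}}, period totals
#' \eqn{X_{\bullet t}} and cluster totals \eqn{X_{k\bullet}},
#' \deqn{DE(r) = \frac{\frac{1}{4} K^2 (1-r)\,[1 + (T-1)r]}
#'   {\left[K X_{\bullet\bullet} - \sum_t X_{\bullet t}^2\right] +
#'    \left[X_{\bullet\bullet}^2 + K(T-1)X_{\bullet\bullet} -
#'          (T-1)\sum_t X_{\bullet t}^2 -
#'          K \sum_k X_{k\bullet}^2\right] r}.}
#' Multiplying the individually randomized sample size by
#' `DE(r) * (1 + (m-1) rho) / m` gives the required number of clusters.
#' DE is invariant to replicating every sequence the same number of times.
#'
#' @param Xc Binary K x T matrix of per-cluster treatment indicators, e.g.
#'   from [expand_to_clusters()].
#' @param r Cluster-period-mean correlation from [compute_r()], in `[0, 1)`.
#' @return Scalar design effect.
#' @export
design_effect <- function(Xc, r) {
  Xc <- as.matrix(Xc)
  stopifnot(r >= 0, r < 1)
  tot <- design_totals(Xc)
  K <- nrow(Xc)
  T <- ncol(Xc)
  U <- tot$grand
  W <- sum(tot$period^2)
  V <- sum(tot$cluster^2)
  denom <- (K * U - W) +
    (U^2 + K * (T - 1) * U - (T - 1) * W - K * V) * r
  if (abs(denom) < 1e-12 * max(1, K^2)) {
    stop("singular-design: no treatment contrast, design effect undefined",
         call. = FALSE)
  }
  0.25 * K^2 * (1 - r) * (1 + (T - 1) * r) / denom
}

#' Sample size for an individually randomized trial
#'
#' The classical two-arm total sample size
#' \deqn{n_i = \frac{4\sigma^2}{(\theta^*)^2}\,(z_{1-\alpha/2} + z_{1-\beta})^2}
#' to detect a mean difference `theta` with two-sided significance `alpha` and
#' power `target_power`. This is the quantity the cluster design effects
#' multiply.
#'
#' @param theta Effect size (difference in means, outcome units; nonzero).
#' @param sigma2 Total outcome variance.
#' @param alpha Two-sided significance level.
#' @param target_power Desired power, in (0, 1).
#' @return Real-valued total number of participants.
#' @export
individually_randomized_n <- function(theta, sigma2, alpha = 0.05,
                                      target_power = 0.8) {
  stopifnot(theta != 0, sigma2 > 0, alpha > 0, alpha < 1,
            target_power > 0, target_power < 1)
  4 * sigma2 / theta^2 *
    (stats::qnorm(1 - alpha / 2) + stats::qnorm(target_power))^2
}

#' GLS variance of the treatment effect estimator
#'
#' Variance of the generalized least squares estimator of the treatment effect
#' from cluster-period means, with categorical period fixed effects and known
#' covariance. With \eqn{X_k} the treatment vector of cluster k and V the
#' common T x T covariance of its cluster-period means,
#' \deqn{\mathrm{var}(\hat\theta) = \left[\sum_k X_k^T V^{-1} X_k -
#'   \left(\sum_k X_k\right)^T V^{-1}
#'   \left(K V^{-1}\right)^{-1} V^{-1} \sum_k X_k\right]^{-1}.}
#' This is the exact variance under either correlation model, for any
#' sampling scheme whose (expected) churn defines V, including per-pair
#' varying churn where the constant-churn design effect does not apply.
#'
#' @param design A [trial_design()]; its expansion supplies the \eqn{X_k}.
#' @param V T x T covariance matrix of cluster-period means, common to all
#'   clusters (from [cov_cluster_period_means()]).
#' @return Scalar variance of the treatment effect estimator.
#' @export
gls_variance <- function(design, V) {
  stopifnot(inherits(design, "trial_design"))
  V <- as.matrix(V)
  if (nrow(V) != design$T || ncol(V) != design$T) {
    stop("V must be T x T for the design's T periods", call. = FALSE)
  }
  if (kappa(V, exact = TRUE) > 1e12) {
    stop("singular-covariance: cluster-period mean covariance is numerically singular",
         call. = FALSE)
  }
  Vi <- solve(V)
  Xc <- expand_to_clusters(design)
  K <- nrow(Xc)
  xvx <- sum(vapply(seq_len(K),
                    function(k) drop(Xc[k, ] %*% Vi %*% Xc[k, ]),
                    numeric(1)))
  xsum <- colSums(Xc)
  info <- xvx - drop(xsum %*% Vi %*% xsum) / K
  if (info <= 1e-12 * sum(diag(Vi))) {
    stop("singular-design: design carries no information about the treatment effect",
         call. = FALSE)
  }
  1 / info
}

# normal-approximation power given the estimator variance
.power_from_variance <- function(var_theta, theta, alpha) {
  stats::pnorm(abs(theta) / sqrt(var_theta) - stats::qnorm(1 - alpha / 2))
}

#' Power of a fixed design via the GLS variance
#'
#' Normal-approximation power
#' \eqn{\Phi(|\theta^*|/\sqrt{\mathrm{var}(\hat\theta)} - z_{1-\alpha/2})}
#' for a two-sided test at level `alpha`; the negligible opposite-tail
#' rejection mass is ignored, consistent with the z-based sample size
#' formulas.
#'
#' @inheritParams gls_variance
#' @param theta Effect size to detect (outcome units).
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1).
#' @export
gls_power <- function(design, V, theta, alpha = 0.05) {
  .power_from_variance(gls_variance(design, V), theta, alpha)
}

#' Power of a fixed design via the design effect
#'
#' The closed-form route for the block-exchangeable model with constant
#' churn: the implied variance is
#' `4 sigma2 DE(r) (1 + (m-1) rho) / (K m)` with `DE` evaluated on the
#' expanded per-cluster matrix. Must agree with [gls_power()] wherever both
#' apply.
#'
#' @param design A [trial_design()].
#' @param vc A [variance_components()] object.
#' @param chi Constant churn rate.
#' @inheritParams gls_power
#' @return Power in (0, 1).
#' @export
design_effect_power <- function(design, vc, chi, theta, alpha = 0.05) {
  Xc <- expand_to_clusters(design)
  r <- compute_r(vc, design$m, chi)
  DE <- design_effect(Xc, r)
  var_theta <- 4 * vc$sigma2 * DE * (1 + (design$m - 1) * vc$rho) /
    (nrow(Xc) * design$m)
  .power_from_variance(var_theta, theta, alpha)
}

#' Required clusters for a longitudinal open-cohort trial
#'
#' Sample-size mode of the design-effect path. Computes the individually
#' randomized total \eqn{n_i}, the cluster-period-mean correlation r, the
#' design effect DE(r) on the schematic (one cluster per sequence), the
#' real-valued required number of clusters
#' \deqn{K_L = DE(r)\,[1 + (m-1)\rho]\,n_i / m,}
#' the parallel-trial requirement \eqn{K_P = [1 + (m-1)\rho]\, n_i/m} for
#' reference, and the integer allocation `ceiling(K_L / S)` clusters per
#' sequence. The achieved power at that integer allocation is recomputed
#' through the GLS path so the rounding cost is visible.
#'
#' @param design A [trial_design()]; its `clusters_per_sequence` is ignored in
#'   sizing (the schematic defines the design), and the returned allocation
#'   replaces it.
#' @param vc A [variance_components()] object.
#' @param chi Constant churn rate in `[0, 1]`.
#' @param theta Effect size to detect (nonzero, outcome units).
#' @param alpha Two-sided significance level.
#' @param target_power Desired power.
#' @return An object of class `power_result`: r, DE, n_i, K_P, K_L (real
#'   valued), `clusters_per_sequence` (integer), `var_theta_hat` and `power`
#'   achieved at the integer allocation.
#' @examples
#' clusters_required(stepped_wedge(3, m = 10),
#'                   variance_components(25, 0.33, 0.9, 0.7),
#'                   chi = 0, theta = 2, target_power = 0.893)
#' @export
clusters_required <- function(design, vc, chi, theta, alpha = 0.05,
                              target_power = 0.8) {
  stopifnot(inherits(design, "trial_design"))
  n_i <- individually_randomized_n(theta, vc$sigma2, alpha, target_power)
  r <- compute_r(vc, design$m, chi)
  schematic_design <- trial_design(design$schematic, rep(1L, design$S),
                                   design$m, design$label)
  DE <- design_effect(expand_to_clusters(schematic_design), r)
  K_P <- (1 + (design$m - 1) * vc$rho) * n_i / design$m
  K_L <- DE * K_P
  per_seq <- as.integer(ceiling(K_L / design$S))
  sized <- trial_design(design$schematic, rep(per_seq, design$S), design$m,
                        design$label)
  V <- cov_matrix_block_exchangeable(vc, scheme_constant_churn(chi),
                                     design$m, design$T)
  var_theta <- gls_variance(sized, V)
  structure(
    list(r = r, DE = DE, n_i = n_i, K_P = K_P, K_L = K_L,
         S = design$S, clusters_per_sequence = per_seq,
         K_total = per_seq * design$S,
         var_theta_hat = var_theta,
         power = .power_from_variance(var_theta, theta, alpha),
         theta = theta, alpha = alpha, target_power = target_power),
    class = "power_result"
  )
}

#' Power across a family of sampling schemes
#'
#' Evaluates power on a grid of scheme parameters through the GLS path,
#' using the covariance model matching the class of `vc`:
#' \describe{
#'   \item{`core_group`}{grid of expected core group proportions in `[0, 1]`
#'     (proportion g corresponds to constant churn 1 - g); proportion 1 is a
#'     closed cohort, proportion 0 repeated cross-sections.}
#'   \item{`in_for_p`}{grid of integer maximum stay lengths p; p = 1 means
#'     one measurement per participant.}
#' }
#'
#' @param design A [trial_design()].
#' @param vc A [variance_components()] or [decay_components()] object.
#' @param family `"core_group"` or `"in_for_p"`.
#' @param grid Scheme parameter values; defaults to proportions 0, 0.1, ..., 1
#'   for `core_group` and 1..T for `in_for_p`.
#' @param theta Effect size.
#' @param alpha Two-sided significance level.
#' @return A data frame with columns `parameter` and `power`.
#' @export
power_curve <- function(design, vc, family = c("core_group", "in_for_p"),
                        grid = NULL, theta, alpha = 0.05) {
  family <- match.arg(family)
  if (is.null(grid)) {
    grid <- switch(family,
                   core_group = seq(0, 1, by = 0.1),
                   in_for_p = seq_len(design$T))
  }
  scheme_of <- switch(family,
                      core_group = function(g) scheme_core_group(g),
                      in_for_p = function(p) scheme_in_for_p(p))
  power <- vapply(grid, function(g) {
    V <- cov_cluster_period_means(vc, scheme_of(g), design$m, design$T)
    gls_power(design, V, theta, alpha)
  }, numeric(1))
  data.frame(parameter = grid, power = power)
}

#' @export
print.power_result <- function(x, ...) {
  cat("Open-cohort longitudinal CRT sample size\n")
  cat(sprintf("  target power %.3f at two-sided alpha %.3f for effect %.3g\n",
              x$target_power, x$alpha, x$theta))
  cat(sprintf("  individually randomized total n_i = %.1f\n", x$n_i))
  cat(sprintf("  r = %.4f, DE(r) = %.4f, K_P = %.2f, K_L = %.2f\n",
              x$r, x$DE, x$K_P, x$K_L))
  cat(sprintf("  required clusters per sequence: %d (total %d over %d sequences)\n",
              x$clusters_per_sequence, x$K_total, x$S))
  cat(sprintf("  achieved power at that allocation: %.4f (var = %.4g)\n",
              x$power, x$var_theta_hat))
  invisible(x)
}
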