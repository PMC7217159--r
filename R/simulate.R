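#' Simulate one open-cohort longitudinal cluster randomized trial
#'
#' Generates individual-level outcome data under the correlation model
#' matching the class of `vc`, with cluster membership realized from the
#' sampling scheme by [realize_panel()].
#'
#' Under the block-exchangeable model each cluster draws a cluster effect, a
#' cluster-period effect per period, one participant effect per distinct
#' participant (reused across all of that participant's periods) and
#' independent residuals. Under the discrete-time decay model the vector of
#' cluster-period effects is drawn jointly with covariance
#' \eqn{\sigma_{CP,D}^2 \pi_D^{|t-s|}}, and each participant's error vector is
#' drawn over exactly the periods they are observed in, with covariance
#' \eqn{\sigma_{\epsilon D}^2 \tau_D^{|t-s|}} restricted to those periods;
#' there is no separate participant random effect.
#'
#' Participants absent from a period simply contribute no record (missing
#' completely at random); `custom` churn tables have no participant-level
#' realization and are not supported.
#'
#' @param design A [trial_design()].
#' @param vc A [variance_components()] or [decay_components()] object.
#' @param scheme A [sampling_scheme()] other than `custom`.
#' @param theta True treatment effect.
#' @param beta_t Period effects, length T; defaults to all zero (the GLS
#'   analysis with period fixed effects is invariant to them).
#' @param seed Optional integer seed.
#' @return A data frame in long format with columns `cluster`, `period`,
#'   `participant` (id stable within cluster), `treatment` and `outcome`;
#'   exactly m rows per cluster-period.
#' @examples
#' d <- stepped_wedge(3, clusters_per_sequence = 1, m = 5)
#' vc <- variance_components(25, 0.33, 0.9, 0.7)
#' head(simulate_trial(d, vc, scheme_in_for_p(2), theta = 2, seed = 1))
#' @export
simulate_trial <- function(design, vc, scheme, theta = 0, beta_t = NULL,
                           seed = NULL) {
  stopifnot(inherits(design, "trial_design"))
  if (!is.null(seed)) set.seed(seed)
  T <- design$T
  m <- design$m
  if (is.null(beta_t)) beta_t <- rep(0, T)
  stopifnot(length(beta_t) == T)
  Xc <- expand_to_clusters(design)
  K <- nrow(Xc)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    panel <- realize_panel(scheme, m, T)
    Y <- .simulate_cluster_outcomes(vc, panel, Xc[k, ], theta, beta_t, m, T)
    out[[k]] <- data.frame(
      cluster = k,
      period = rep(seq_len(T), each = m),
      participant = unlist(panel, use.names = FALSE),
      treatment = rep(Xc[k, ], each = m),
      outcome = as.vector(Y)
    )
  }
  do.call(rbind, out)
}

# m x T outcome matrix; entry [j, t] belongs to participant panel[[t]][j]
.simulate_cluster_outcomes <- function(vc, panel, xrow, theta, beta_t, m, T) {
  if (inherits(vc, "vc_block_exchangeable")) {
    ids <- unique(unlist(panel, use.names = FALSE))
    eta <- stats::rnorm(length(ids), 0, sqrt(vc$sigma_eta2))
    C <- stats::rnorm(1L, 0, sqrt(vc$sigma_C2))
    CP <- stats::rnorm(T, 0, sqrt(vc$sigma_CP2))
    Y <- matrix(stats::rnorm(m * T, 0, sqrt(vc$sigma_eps2)), m, T)
    for (t in seq_len(T)) {
      Y[, t] <- Y[, t] + beta_t[t] + theta * xrow[t] + C + CP[t] +
        eta[match(panel[[t]], ids)]
    }
    Y
  } else if (inherits(vc, "vc_decay")) {
    lag <- abs(outer(seq_len(T), seq_len(T), "-"))
    CPk <- drop(.cov_factor(vc$sigma_CP2 * vc$pi_D^lag) %*% stats::rnorm(T))
    Y <- matrix(0, m, T)
    occ_period <- rep(seq_len(T), each = m)
    occ_slot <- rep(seq_len(m), times = T)
    by_id <- split(seq_along(occ_period), unlist(panel, use.names = FALSE))
    key <- vapply(by_id, function(ix) paste(occ_period[ix], collapse = ","),
                  character(1))
    for (grp in split(by_id, key)) {
      P <- occ_period[grp[[1L]]]
      L <- .cov_factor(vc$sigma_eps2 * vc$tau_D^abs(outer(P, P, "-")))
      E <- matrix(stats::rnorm(length(grp) * length(P)),
                  nrow = length(grp)) %*% t(L)
      for (g in seq_along(grp)) {
        ix <- grp[[g]]
        Y[cbind(occ_slot[ix], occ_period[ix])] <- E[g, ]
      }
    }
    sweep(Y, 2L, beta_t + theta * xrow + CPk, "+")
  } else {
    stop("vc must be a variance_components() or decay_components() object",
         call. = FALSE)
  }
}

# lower-triangular-ish factor L with L %*% t(L) = Sigma; tolerates PSD
# matrices (e.g. decay parameter exactly 1)
.cov_factor <- function(Sigma) {
  if (length(Sigma) == 1L) return(matrix(sqrt(max(Sigma, 0)), 1L, 1L))
  L <- tryCatch(t(chol(Sigma)), error = function(e) NULL)
  if (is.null(L)) {
    e <- eigen(Sigma, symmetric = TRUE)
    L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(Sigma))
  }
  L
}

#' Simulate cluster-period means across replicate trials
#'
#' Replicated generation of the K x T matrix of cluster-period means, the
#' sufficient statistic the analytic covariance models describe. Replicate j
#' reseeds deterministically with `seed + j`, so extending `replicates` never
#' changes earlier replicates.
#'
#' @inheritParams simulate_trial
#' @param replicates Number of replicate trials.
#' @param seed Base integer seed.
#' @return A `replicates` x K x T array of cluster-period means.
#' @export
simulate_cluster_period_means <- function(design, vc, scheme, theta = 0,
                                          beta_t = NULL, replicates = 1000,
                                          seed = 1) {
  stopifnot(inherits(design, "trial_design"), replicates >= 1)
  T <- design$T
  m <- design$m
  if (is.null(beta_t)) beta_t <- rep(0, T)
  Xc <- expand_to_clusters(design)
  K <- nrow(Xc)
  means <- array(NA_real_, dim = c(replicates, K, T))
  for (j in seq_len(replicates)) {
    set.seed(seed + j)
    for (k in seq_len(K)) {
      panel <- realize_panel(scheme, m, T)
      Y <- .simulate_cluster_outcomes(vc, panel, Xc[k, ], theta, beta_t, m, T)
      means[j, k, ] <- colMeans(Y)
    }
  }
  means
}

#' Empirical power by Monte Carlo
#'
#' Simulates replicate trials, collapses each to cluster-period means,
#' computes the GLS treatment effect estimate using the true (analytic)
#' covariance and its variance, and rejects when
#' \eqn{|\hat\theta|/\sqrt{\mathrm{var}(\hat\theta)} > z_{1-\alpha/2}}.
#' The rejection fraction estimates the power of the design; at `theta = 0`
#' it estimates the type I error rate.
#'
#' @inheritParams simulate_cluster_period_means
#' @param alpha Two-sided significance level.
#' @return An object of class `empirical_power`: a list with `power`
#'   (rejection fraction), `se` (binomial Monte Carlo standard error),
#'   `theta_hat` (vector of replicate estimates), `var_theta_hat` (analytic
#'   GLS variance used for the test), `analytic_power`, `replicates`.
#' @examples
#' d <- stepped_wedge(3, clusters_per_sequence = 2, m = 5)
#' vc <- variance_components(25, 0.33, 0.9, 0.7)
#' empirical_power(d, vc, scheme_constant_churn(0), theta = 2,
#'                 replicates = 200, seed = 1)
#' @export
empirical_power <- function(design, vc, scheme, theta, alpha = 0.05,
                            beta_t = NULL, replicates = 1000, seed = 1) {
  stopifnot(alpha > 0, alpha < 1)
  V <- cov_cluster_period_means(vc, scheme, design$m, design$T)
  var_theta <- gls_variance(design, V)
  Vi <- solve(V)
  Xc <- expand_to_clusters(design)
  # theta_hat = var_theta * sum_k (X_k - Xbar)' V^{-1} ybar_k
  wts <- var_theta * (sweep(Xc, 2L, colMeans(Xc)) %*% Vi)
  means <- simulate_cluster_period_means(design, vc, scheme, theta, beta_t,
                                         replicates, seed)
  theta_hat <- vapply(seq_len(replicates),
                      function(j) sum(wts * means[j, , ]), numeric(1))
  zcrit <- stats::qnorm(1 - alpha / 2)
  rej <- mean(abs(theta_hat) / sqrt(var_theta) > zcrit)
  structure(
    list(power = rej,
         se = sqrt(rej * (1 - rej) / replicates),
         theta_hat = theta_hat,
         var_theta_hat = var_theta,
         analytic_power = .power_from_variance(var_theta, theta, alpha),
         replicates = replicates, theta = theta, alpha = alpha),
    class = "empirical_power"
  )
}

#' @export
print.empirical_power <- function(x, ...) {
  cat(sprintf("Empirical power: %.4f (MC se %.4f, %d replicates)\n",
              x$power, x$se, x$replicates))
  cat(sprintf("  analytic power %.4f at theta = %.3g, alpha = %.3f\n",
              x$analytic_power, x$theta, x$alpha))
  invisible(x)
}
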