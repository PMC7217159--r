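#' Open-cohort sampling schemes
#'
#' An open-cohort sampling scheme specifies, for every pair of distinct
#' periods (t, s), the churn rate \eqn{\chi(t,s)}: the expected proportion of
#' the m participants measured in period t who are not measured in period s.
#' The retention rate is \eqn{1 - \chi(t,s)}, and the expected number of
#' participants observed in both periods is \eqn{n(t,s) = m(1-\chi(t,s))}.
#'
#' Five kinds are supported:
#' \describe{
#'   \item{`constant_churn`}{A core group of `m * (1 - chi)` participants is
#'     measured in every period; the remaining slots are filled each period by
#'     fresh participants measured once. Churn is the same constant `chi` for
#'     every period pair. `chi = 0` is a closed cohort; `chi = 1` is repeated
#'     cross-sectional sampling.}
#'   \item{`closed_population`}{Each period an independent simple random
#'     sample of m participants is drawn from a fixed population of size `M`,
#'     so the expected churn between any two periods is `1 - m/M`.}
#'   \item{`beta_churn`}{Each cluster's churn rate is drawn once from a
#'     Beta(`alpha`, `beta`) distribution with `alpha + beta = m` (`alpha` the
#'     expected number lost, `beta` the expected number retained between
#'     consecutive periods); the analytic path uses the expectation
#'     `alpha/(alpha + beta)`.}
#'   \item{`in_for_p`}{Rotation sampling: each participant is measured in at
#'     most `p` consecutive periods and a fraction 1/p of each cluster's
#'     sample is replaced at each period, so
#'     \eqn{\chi(t,s) = \min(|t-s|/p, 1)}.}
#'   \item{`custom`}{An arbitrary symmetric T x T table of churn rates with
#'     zero diagonal. Validated by checking the implied covariance matrix is
#'     positive semidefinite.}
#' }
#'
#' @param kind One of `"constant_churn"`, `"closed_population"`,
#'   `"beta_churn"`, `"in_for_p"`, `"custom"`.
#' @param chi Constant churn rate in `[0, 1]` (`constant_churn` only).
#' @param M Population size per cluster (`closed_population` only).
#' @param alpha,beta Beta distribution parameters (`beta_churn` only).
#' @param p Maximum number of consecutive periods a participant is measured in
#'   (`in_for_p` only, at least 1).
#' @param table Symmetric churn matrix with zero diagonal (`custom` only).
#' @return An object of class `sampling_scheme`.
#' @examples
#' sampling_scheme("constant_churn", chi = 0.3)
#' scheme_in_for_p(2)
#' @export
sampling_scheme <- function(kind = c("constant_churn", "closed_population",
                                     "beta_churn", "in_for_p", "custom"),
                            chi = NULL, M = NULL, alpha = NULL, beta = NULL,
                            p = NULL, table = NULL) {
  kind <- match.arg(kind)
  given <- c(chi = !is.null(chi), M = !is.null(M),
             alpha = !is.null(alpha) || !is.null(beta),
             p = !is.null(p), table = !is.null(table))
  needed <- switch(kind,
    constant_churn    = "chi",
    closed_population = "M",
    beta_churn        = "alpha",
    in_for_p          = "p",
    custom            = "table")
  if (!given[[needed]] || any(given[setdiff(names(given), needed)])) {
    stop(sprintf("invalid-scheme: kind '%s' takes exactly its own fields", kind),
         call. = FALSE)
  }
  out <- list(kind = kind)
  switch(kind,
    constant_churn = {
      stopifnot(is.numeric(chi), length(chi) == 1L, chi >= 0, chi <= 1)
      out$chi <- chi
    },
    closed_population = {
      stopifnot(is.numeric(M), length(M) == 1L, M >= 1)
      out$M <- as.integer(M)
    },
    beta_churn = {
      if (is.null(alpha) || is.null(beta)) {
        stop("invalid-scheme: beta_churn needs both alpha and beta", call. = FALSE)
      }
      stopifnot(alpha > 0, beta > 0)
      out$alpha <- alpha
      out$beta <- beta
    },
    in_for_p = {
      stopifnot(is.numeric(p), length(p) == 1L, p >= 1)
      out$p <- as.integer(p)
    },
    custom = {
      table <- as.matrix(table)
      if (nrow(table) != ncol(table) || any(abs(table - t(table)) > 1e-12) ||
          any(diag(table) != 0) || any(table < 0) || any(table > 1)) {
        stop("invalid-scheme: custom churn table must be symmetric in [0,1] with zero diagonal",
             call. = FALSE)
      }
      out$table <- table
    })
  class(out) <- "sampling_scheme"
  out
}

#' @rdname sampling_scheme
#' @export
scheme_constant_churn <- function(chi) sampling_scheme("constant_churn", chi = chi)

#' Core-group scheme by core proportion
#'
#' Convenience wrapper: a core-group scheme in which a proportion `core` of
#' each cluster-period sample is measured in every period is a constant-churn
#' scheme with `chi = 1 - core`.
#'
#' @param core Expected core group proportion in `[0, 1]`.
#' @export
scheme_core_group <- function(core) {
  stopifnot(core >= 0, core <= 1)
  sampling_scheme("constant_churn", chi = 1 - core)
}

#' @rdname sampling_scheme
#' @export
scheme_closed_population <- function(M) sampling_scheme("closed_population", M = M)

#' @rdname sampling_scheme
#' @export
scheme_beta_churn <- function(alpha, beta) {
  sampling_scheme("beta_churn", alpha = alpha, beta = beta)
}

#' @rdname sampling_scheme
#' @export
scheme_in_for_p <- function(p) sampling_scheme("in_for_p", p = p)

#' @rdname sampling_scheme
#' @export
scheme_custom <- function(table) sampling_scheme("custom", table = table)

#' Expected churn rate between two periods
#'
#' Evaluates the (expected) churn rate \eqn{\chi(t,s)} of a sampling scheme for
#' a pair of distinct periods. For `beta_churn` the expectation
#' `alpha/(alpha + beta)` is returned, which is all the covariance of
#' cluster-period means depends on.
#'
#' @param scheme A [sampling_scheme()].
#' @param t,s Distinct period indices (1-based).
#' @param m Cluster-period size; required to evaluate `closed_population`
#'   (churn `1 - m/M`) and to validate `beta_churn` (`alpha + beta` must equal
#'   `m`).
#' @return Churn rate in `[0, 1]`.
#' @export
expected_churn <- function(scheme, t, s, m) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  if (any(t == s)) {
    stop("invalid-pair: churn is defined only for distinct periods (diagonal churn is identically 0)",
         call. = FALSE)
  }
  switch(scheme$kind,
    constant_churn = rep_len(scheme$chi, length(t)),
    closed_population = {
      if (scheme$M < m) {
        stop("invalid-scheme: closed population size M must be at least m", call. = FALSE)
      }
      rep_len(1 - m / scheme$M, length(t))
    },
    beta_churn = {
      if (abs(scheme$alpha + scheme$beta - m) > 1e-8) {
        stop("invalid-scheme: beta_churn requires alpha + beta = m", call. = FALSE)
      }
      rep_len(scheme$alpha / (scheme$alpha + scheme$beta), length(t))
    },
    in_for_p = pmin(abs(t - s) / scheme$p, 1),
    custom = {
      if (any(t > nrow(scheme$table)) || any(s > nrow(scheme$table))) {
        stop("invalid-scheme: custom churn table smaller than requested period",
             call. = FALSE)
      }
      scheme$table[cbind(t, s)]
    })
}

#' Churn matrix of a scheme over T periods
#'
#' @inheritParams expected_churn
#' @param T Number of periods.
#' @return T x T matrix of expected churn rates with zero diagonal.
#' @export
churn_matrix <- function(scheme, T, m) {
  idx <- which(row(diag(T)) != col(diag(T)), arr.ind = TRUE)
  chi <- matrix(0, T, T)
  chi[idx] <- expected_churn(scheme, idx[, 1L], idx[, 2L], m)
  chi
}

#' @export
print.sampling_scheme <- function(x, ...) {
  cat("Open-cohort sampling scheme:", x$kind, "\n")
  parms <- x[setdiff(names(x), "kind")]
  if (x$kind == "custom") {
    print(x$table)
  } else if (length(parms)) {
    cat(" ", paste(sprintf("%s = %g", names(parms), unlist(parms)),
                   collapse = ", "), "\n")
  }
  invisible(x)
}
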