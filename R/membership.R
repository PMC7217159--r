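#' Membership (overlap) matrix of an open cohort
#'
#' `membership_matrix()` validates and wraps a T x T matrix of overlap counts
#' n(t, s): the number of participants in a cluster measured in both periods t
#' and s. A valid overlap matrix is symmetric with n(t, t) = m, entries in
#' `[0, m]`, and must satisfy, for every triple of periods (t, u, s),
#' \deqn{n(t,u) + n(u,s) \le n(t,s) + m,}
#' because participants present in periods t and u, and those present in u and
#' s, cannot together exceed the m participants of period u plus those present
#' in both t and s.
#'
#' @param n Integer T x T matrix of overlap counts.
#' @param m Cluster-period size.
#' @return An object of class `membership_matrix` (a list with `n` and `m`).
#' @export
membership_matrix <- function(n, m) {
  n <- as.matrix(n)
  storage.mode(n) <- "integer"
  T <- nrow(n)
  if (ncol(n) != T) stop("overlap matrix must be square", call. = FALSE)
  if (any(n != t(n))) {
    stop("construction-failure: overlap matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(n) != m)) {
    stop("construction-failure: diagonal overlaps must equal m", call. = FALSE)
  }
  if (any(n < 0L) || any(n > m)) {
    stop("construction-failure: overlaps must lie in [0, m]", call. = FALSE)
  }
  if (!.triple_inequality_holds(n, m)) {
    stop("construction-failure: overlap counts violate the triple inequality n(t,u) + n(u,s) <= n(t,s) + m",
         call. = FALSE)
  }
  structure(list(n = n, m = as.integer(m)), class = "membership_matrix")
}

.triple_inequality_holds <- function(n, m) {
  T <- nrow(n)
  for (u in seq_len(T)) {
    # lhs[t, s] = n(t, u) + n(u, s)
    lhs <- outer(n[, u], n[u, ], "+")
    if (any(lhs > n + m)) return(FALSE)
  }
  TRUE
}

#' Realize a per-period participant panel under a sampling scheme
#'
#' Draws one cluster's concrete membership: which participant provides a
#' measurement in which period. Used by the trial simulator and by
#' [realize_membership()].
#'
#' Realizations follow the scheme definitions:
#' \itemize{
#'   \item `constant_churn`: a fixed core set of `round(m (1 - chi))`
#'     participants (half-up rounding) appears in every period; remaining
#'     slots are filled by fresh single-measurement participants each period.
#'   \item `closed_population`: an independent simple random sample of m
#'     participants from the pool `1..M` each period; participants may return
#'     after an absence.
#'   \item `beta_churn`: the cluster's churn is drawn once from
#'     Beta(alpha, beta), then a core-group panel is built with that churn.
#'   \item `in_for_p`: a rotating panel of p concurrent entry cohorts; each
#'     cohort stays for p consecutive periods and one cohort is replaced each
#'     period. When m is not divisible by p, cohort sizes are
#'     `floor(m/p)` or `ceiling(m/p)`, the larger sizes allocated
#'     deterministically to the first `m %% p` rotation positions.
#' }
#' `custom` tables specify only pairwise counts, which do not determine a
#' participant-level panel, and are not supported here.
#'
#' Randomness (closed-population sampling, Beta churn draws) uses the current
#' RNG state; seed with [set.seed()] for reproducibility.
#'
#' @inheritParams expected_churn
#' @param T Number of periods.
#' @return List of length T; element t is the integer vector (length m) of
#'   participant ids measured in period t. Ids are stable within the cluster.
#' @export
realize_panel <- function(scheme, m, T) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  switch(scheme$kind,
    constant_churn = .core_group_panel(scheme$chi, m, T),
    beta_churn = {
      if (abs(scheme$alpha + scheme$beta - m) > 1e-8) {
        stop("invalid-scheme: beta_churn requires alpha + beta = m", call. = FALSE)
      }
      .core_group_panel(stats::rbeta(1L, scheme$alpha, scheme$beta), m, T)
    },
    closed_population = {
      if (scheme$M < m) {
        stop("invalid-scheme: closed population size M must be at least m",
             call. = FALSE)
      }
      lapply(seq_len(T), function(t) sample.int(scheme$M, m))
    },
    in_for_p = .rotation_panel(scheme$p, m, T),
    custom = stop("invalid-scheme: custom churn tables specify counts only and cannot be realized as a panel",
                  call. = FALSE)
  )
}

.round_half_up <- function(x) floor(x + 0.5)

.core_group_panel <- function(chi, m, T) {
  core <- .round_half_up(m * (1 - chi))
  core_ids <- seq_len(core)
  nxt <- core
  panel <- vector("list", T)
  for (t in seq_len(T)) {
    fresh <- if (core < m) nxt + seq_len(m - core) else integer(0)
    nxt <- nxt + (m - core)
    panel[[t]] <- c(core_ids, fresh)
  }
  panel
}

.rotation_panel <- function(p, m, T) {
  p <- as.integer(p)
  m <- as.integer(m)
  base <- m %/% p
  rem <- m %% p
  cohort_size <- function(j) {
    res <- ((j - 1L) %% p + p) %% p
    base + as.integer(res < rem)
  }
  # Cohort j enters at period j (j <= 1 are cohorts already underway at the
  # start) and stays for periods j .. j + p - 1.
  entries <- seq.int(2L - p, T)
  sizes <- vapply(entries, cohort_size, integer(1))
  offsets <- c(0L, cumsum(sizes))
  ids <- function(idx) offsets[idx] + seq_len(sizes[idx])
  panel <- vector("list", T)
  for (t in seq_len(T)) {
    active <- which(entries > t - p & entries <= t)
    panel[[t]] <- unlist(lapply(active, ids), use.names = FALSE)
  }
  panel
}

.membership_from_panel <- function(panel, m) {
  T <- length(panel)
  n <- matrix(0L, T, T)
  for (t in seq_len(T)) {
    for (s in t:T) {
      n[t, s] <- n[s, t] <- length(intersect(panel[[t]], panel[[s]]))
    }
  }
  membership_matrix(n, m)
}

#' Realize a membership matrix under a sampling scheme
#'
#' Draws (or, for deterministic schemes, constructs) one cluster's T x T
#' overlap-count matrix. For `constant_churn`, `beta_churn`,
#' `closed_population` and `in_for_p` the counts come from an actual
#' participant panel built by [realize_panel()], so all
#' [membership_matrix()] invariants hold by construction. For `custom`
#' tables the counts are `round(m (1 - chi(t,s)))` (half-up); a table whose
#' rounded counts violate the triple inequality signals
#' `construction-failure`.
#'
#' @inheritParams realize_panel
#' @param seed Optional integer seed applied via [set.seed()] before drawing.
#' @return A [membership_matrix()].
#' @examples
#' set.seed(1)
#' realize_membership(scheme_in_for_p(2), m = 10, T = 4)$n
#' @export
realize_membership <- function(scheme, m, T, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (scheme$kind == "custom") {
    if (nrow(scheme$table) < T) {
      stop("invalid-scheme: custom churn table smaller than requested period",
           call. = FALSE)
    }
    n <- .round_half_up(m * (1 - scheme$table[seq_len(T), seq_len(T), drop = FALSE]))
    diag(n) <- m
    return(membership_matrix(n, m))
  }
  .membership_from_panel(realize_panel(scheme, m, T), m)
}

#' @export
print.membership_matrix <- function(x, ...) {
  cat(sprintf("Overlap counts for one cluster (m = %d per period)\n", x$m))
  n <- x$n
  dimnames(n) <- rep(list(paste0("period_", seq_len(nrow(n)))), 2)
  print(n)
  invisible(x)
}
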