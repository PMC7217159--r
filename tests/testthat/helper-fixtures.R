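# Shared fixtures: the school-based stepped wedge configuration used as the
# running worked example (3 sequences, T = 4, m = 10, sigma2 = 25, rho = 0.33,
# pi = 0.9, tau = 0.7, effect 2, two-sided alpha 0.05).

school_design <- function(clusters_per_sequence = 4L) {
  stepped_wedge(3, clusters_per_sequence = clusters_per_sequence, m = 10)
}

school_vc <- function() variance_components(25, 0.33, 0.9, 0.7)

# Independent brute-force oracle for the GLS variance: assemble the full
# KT x KT covariance of all cluster-period means (block diagonal), the full
# fixed-effects design matrix (T period indicators plus the treatment column),
# and invert the complete information matrix.
brute_force_gls_variance <- function(design, V) {
  Xc <- expand_to_clusters(design)
  K <- nrow(Xc)
  T <- ncol(Xc)
  Vfull <- matrix(0, K * T, K * T)
  for (k in seq_len(K)) {
    idx <- (k - 1) * T + seq_len(T)
    Vfull[idx, idx] <- V
  }
  period_dummies <- diag(T)[rep(seq_len(T), times = K), ]
  Z <- cbind(period_dummies, as.vector(t(Xc)))
  info <- t(Z) %*% solve(Vfull) %*% Z
  solve(info)[T + 1, T + 1]
}

# Overlap counts recomputed from a simulated long-format dataset.
overlap_from_dataset <- function(dataset, cluster, T) {
  d <- dataset[dataset$cluster == cluster, ]
  ids <- lapply(seq_len(T), function(t) d$participant[d$period == t])
  n <- matrix(0L, T, T)
  for (t in seq_len(T)) {
    for (s in seq_len(T)) {
      n[t, s] <- length(intersect(ids[[t]], ids[[s]]))
    }
  }
  n
}
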