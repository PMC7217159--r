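test_that("block-exchangeable components are nonnegative and sum to sigma2", {
  for (rho in c(0, 0.05, 0.33, 0.9)) {
    for (tau in c(0, 0.7, 1)) {
      vc <- variance_components(25, rho, pi = 0.9, tau = tau)
      comps <- c(vc$sigma_C2, vc$sigma_CP2, vc$sigma_eta2, vc$sigma_eps2)
      expect_true(all(comps >= 0))
      expect_equal(sum(comps), 25)
    }
  }
  vc <- variance_components(25, 0.33, 0.9, 0.7)
  expect_equal(vc$sigma_C2, 25 * 0.33 * 0.9)
  expect_equal(vc$sigma_eta2, 25 * 0.67 * 0.7)
  # pi is not needed (treated as 0) when rho = 0
  expect_equal(variance_components(4, 0, tau = 0.5)$pi, 0)
  expect_error(variance_components(4, 0.2, tau = 0.5), "pi must be supplied")
})

test_that("decay components split the total variance by rho", {
  vc <- decay_components(25, 0.33, 0.94, 0.80)
  expect_equal(vc$sigma_CP2, 25 * 0.33)
  expect_equal(vc$sigma_eps2, 25 * 0.67)
})

test_that("expected churn matches each scheme's definition", {
  expect_equal(expected_churn(scheme_closed_population(10), 1, 2, m = 10), 0)
  expect_equal(expected_churn(scheme_closed_population(40), 1, 2, m = 10), 0.75)
  expect_equal(expected_churn(scheme_in_for_p(2), 1, 2, m = 10), 0.5)
  expect_equal(expected_churn(scheme_in_for_p(2), 1, 4, m = 10), 1)
  expect_equal(expected_churn(scheme_beta_churn(3, 7), 2, 4, m = 10), 0.3)
  expect_equal(expected_churn(scheme_constant_churn(0.25), 1, 3, m = 6), 0.25)
  tab <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  expect_equal(expected_churn(scheme_custom(tab), 2, 1, m = 5), 0.2)
  expect_error(expected_churn(scheme_constant_churn(0.2), 3, 3, m = 5),
               "invalid-pair")
  expect_error(expected_churn(scheme_closed_population(5), 1, 2, m = 10),
               "invalid-scheme")
  expect_error(expected_churn(scheme_beta_churn(3, 8), 1, 2, m = 10),
               "invalid-scheme")
})

test_that("closed-population expected churn agrees with repeated-sampling simulation", {
  m <- 10; M <- 40
  set.seed(11)
  overlap <- replicate(3000, {
    length(intersect(sample.int(M, m), sample.int(M, m))) / m
  })
  # E[overlap/m] = m/M = 1 - churn
  expect_equal(mean(1 - overlap),
               expected_churn(scheme_closed_population(M), 1, 2, m),
               tolerance = 0.02)
})

test_that("scheme constructor enforces one-kind-one-set-of-fields", {
  expect_error(sampling_scheme("constant_churn", chi = 0.2, p = 3),
               "invalid-scheme")
  expect_error(sampling_scheme("in_for_p"), "invalid-scheme")
  expect_error(scheme_custom(matrix(c(0, 0.3, 0.4, 0), 2, 2)), "symmetric")
  expect_error(scheme_custom(matrix(c(0.1, 0.3, 0.3, 0), 2, 2)), "zero diagonal")
})

test_that("block-exchangeable covariance has the churn-weighted structure", {
  vc <- school_vc()
  m <- 10; T <- 4
  diag_expected <- vc$sigma_C2 + vc$sigma_CP2 +
    (vc$sigma_eta2 + vc$sigma_eps2) / m

  V1 <- cov_matrix_block_exchangeable(vc, scheme_constant_churn(1), m, T)
  expect_equal(unique(V1[upper.tri(V1)]), vc$sigma_C2)
  V0 <- cov_matrix_block_exchangeable(vc, scheme_constant_churn(0), m, T)
  expect_equal(unique(V0[upper.tri(V0)]), vc$sigma_C2 + vc$sigma_eta2 / m)
  expect_equal(diag(V0), rep(diag_expected, T))

  V3 <- cov_matrix_block_exchangeable(vc, scheme_constant_churn(0.3), m, T)
  expect_equal(unique(V3[upper.tri(V3)]),
               25 * 0.33 * 0.9 + 25 * 0.67 * 0.7 * 0.7 / 10)
})

test_that("decay covariance degenerates to block-exchangeable at decay 1", {
  sigma2 <- 25; rho <- 0.33; m <- 10; T <- 5
  vc_be <- variance_components(sigma2, rho, pi = 1, tau = 1)
  vc_d <- decay_components(sigma2, rho, pi_D = 1, tau_D = 1)
  for (scheme in list(scheme_constant_churn(0.3), scheme_in_for_p(2),
                      scheme_closed_population(40))) {
    Vb <- cov_matrix_block_exchangeable(vc_be, scheme, m, T)
    Vd <- cov_matrix_decay(vc_d, scheme, m, T)
    expect_equal(Vb, Vd, tolerance = 1e-12)
  }
})

test_that("in-for-p decay covariance loses the participant term beyond lag p", {
  vc <- decay_components(25, 0.33, 0.94, 0.80)
  V <- cov_matrix_decay(vc, scheme_in_for_p(2), m = 10, T = 4)
  expect_equal(V[1, 3], vc$sigma_CP2 * 0.94^2)    # churn 1 at lag 2
  expect_equal(V[1, 2], vc$sigma_CP2 * 0.94 + (vc$sigma_eps2 / 10) * 0.80 * 0.5)
  expect_equal(V[1, 4], vc$sigma_CP2 * 0.94^3)
})

test_that("covariance matrices are positive semidefinite across schemes", {
  schemes <- list(scheme_constant_churn(0), scheme_constant_churn(0.3),
                  scheme_constant_churn(1), scheme_in_for_p(1),
                  scheme_in_for_p(3), scheme_closed_population(40),
                  scheme_beta_churn(3, 7))
  for (scheme in schemes) {
    for (V in list(cov_matrix_block_exchangeable(school_vc(), scheme, 10, 6),
                   cov_matrix_decay(decay_components(25, 0.33, 0.94, 0.8),
                                    scheme, 10, 6))) {
      expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-10)
    }
  }
})

test_that("an unrealizable custom churn table is rejected as non-PSD", {
  # claims full retention between (1,2) and (2,3) but none between (1,3):
  # impossible for any membership process
  tab <- matrix(c(0, 0, 1,
                  0, 0, 0,
                  1, 0, 0), 3, 3)
  vc <- variance_components(1, 0.01, pi = 0, tau = 1)
  expect_error(
    cov_matrix_block_exchangeable(vc, scheme_custom(tab), m = 1, T = 3),
    "invalid-scheme"
  )
  expect_error(realize_membership(scheme_custom(tab), m = 10, T = 3),
               "construction-failure")
})

test_that("realized membership matrices satisfy all invariants", {
  set.seed(13)
  schemes <- list(scheme_constant_churn(0.3), scheme_closed_population(25),
                  scheme_in_for_p(2), scheme_in_for_p(3),
                  scheme_beta_churn(3, 7))
  for (scheme in schemes) {
    for (rep in 1:40) {
      mm <- realize_membership(scheme, m = 10, T = 5)
      expect_s3_class(mm, "membership_matrix")  # constructor validates
      expect_equal(diag(mm$n), rep(10L, 5))
      expect_true(all(mm$n == t(mm$n)))
    }
  }
})

test_that("named schemes realize their stated overlap counts", {
  expect_true(all(realize_membership(scheme_constant_churn(0), 10, 4)$n == 10))
  n2 <- realize_membership(scheme_in_for_p(2), 10, 4)$n
  expect_equal(n2[cbind(1:3, 2:4)], rep(5L, 3))
  expect_equal(n2[1, 3], 0L)
  expect_equal(n2[1, 4], 0L)
  # core group: round(m(1 - chi)) shared everywhere
  n3 <- realize_membership(scheme_constant_churn(0.3), 10, 4)$n
  expect_true(all(n3[upper.tri(n3)] == 7L))
  # half-up rounding of m(1 - chi)
  n4 <- realize_membership(scheme_constant_churn(0.25), 10, 4)$n
  expect_true(all(n4[upper.tri(n4)] == 8L))
})

test_that("closed-population overlap averages m^2/M", {
  m <- 10; M <- 20
  set.seed(17)
  draws <- replicate(1500, realize_membership(scheme_closed_population(M), m, 3)$n[1, 2])
  # hypergeometric overlap: mean m^2/M, variance m (m/M) (1 - m/M) (M-m)/(M-1)
  se <- sqrt(m * (m / M) * (1 - m / M) * (M - m) / (M - 1) / 1500)
  expect_lt(abs(mean(draws) - m^2 / M), 3 * se)
})

test_that("Beta churn realizations reproduce the analytic between-period covariance", {
  m <- 100; alpha <- 30; beta <- 70
  vc <- variance_components(25, 0.33, 0.9, 0.7)
  analytic <- vc$sigma_C2 + vc$sigma_eta2 * (beta / (alpha + beta)) / m
  expect_equal(
    cov_matrix_block_exchangeable(vc, scheme_beta_churn(alpha, beta), m, 3)[1, 2],
    analytic
  )
  set.seed(19)
  emp <- replicate(600, {
    n <- realize_membership(scheme_beta_churn(alpha, beta), m, 2)$n[1, 2]
    vc$sigma_C2 + vc$sigma_eta2 * n / m^2
  })
  se <- stats::sd(emp) / sqrt(length(emp))
  expect_lt(abs(mean(emp) - analytic), 3 * se + 1e-12)
})

test_that("triple inequality holds exhaustively for realized matrices", {
  set.seed(23)
  for (T in c(4, 8)) {
    for (scheme in list(scheme_closed_population(15), scheme_in_for_p(3),
                        scheme_beta_churn(4, 6))) {
      n <- realize_membership(scheme, m = 10, T = T)$n
      for (t in 1:T) for (u in 1:T) for (s in 1:T) {
        expect_lte(n[t, u] + n[u, s], n[t, s] + 10)
      }
    }
  }
})

test_that("membership matrices round-trip to CSV", {
  mm <- realize_membership(scheme_in_for_p(2), 10, 4, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_membership(mm, path)
  back <- as.matrix(utils::read.csv(path))
  expect_equal(unname(back), unname(mm$n), ignore_attr = TRUE)
  unlink(path)
})
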