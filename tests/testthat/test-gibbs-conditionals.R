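# Each full-conditional update, with everything else held fixed, must draw
# from its stated closed form.  Normal / scaled-inv-chi-square / gamma
# conditionals are checked by KS tests against CDFs whose parameters are
# recomputed independently in the test.

test_that("nb_log_pmf matches hand values and the standard NB pmf", {
  expect_equal(nb_log_pmf(0, 0, 1), log(1 / 2), tolerance = 1e-12)
  expect_equal(nb_log_pmf(2, 0, 2), log(3 / 16), tolerance = 1e-12)
  # logistic form == NB(mu = r exp(eta*), size = r) across a grid
  set.seed(21)
  for (i in 1:20) {
    y <- rpois(1, 4); eta <- rnorm(1, 0, 2); r <- runif(1, 0.2, 50)
    expect_equal(nb_log_pmf(y, eta, r),
                 dnbinom(y, size = r, mu = r * exp(eta), log = TRUE),
                 tolerance = 1e-9)
  }
  # overflow safety at extreme predictors
  expect_true(is.finite(nb_log_pmf(3, 100, 2)))
  expect_true(is.finite(nb_log_pmf(0, -100, 2)))
  expect_error(nb_log_pmf(-1, 0, 1), "non-negative")
  expect_error(nb_log_pmf(1, 0, -1), "positive")
})

test_that("fixed-effect update draws from its closed-form normal", {
  set.seed(31)
  n <- 6; p <- 2
  X <- cbind(1, c(0, 0, 0, 1, 1, 1))
  omega <- runif(n, 0.2, 2)
  kappa <- rnorm(n)
  zb <- rnorm(n, 0, 0.5)
  prior <- prior_spec(p = p, beta0 = c(0.5, -0.2), Sigma0 = 2)
  # independent recomputation of the conditional moments
  S0inv <- solve(diag(2, p))
  Sig <- solve(S0inv + t(X) %*% diag(omega) %*% X)
  mu <- Sig %*% (S0inv %*% c(0.5, -0.2) + t(X) %*% (kappa - omega * zb))
  draws <- t(replicate(5000, update_beta(omega, kappa, X, zb, prior, 1)))
  for (j in 1:p)
    expect_gt(ks.test(draws[, j], pnorm, mean = mu[j],
                      sd = sqrt(Sig[j, j]))$p.value, 0.01)
  expect_equal(cov(draws), Sig, tolerance = 0.1)

  # overwhelming prior precision pins the draw at beta0
  tight <- prior_spec(p = p, beta0 = c(0.5, -0.2), Sigma0 = 1e-10)
  d <- update_beta(omega, kappa, X, zb, tight, 1)
  expect_equal(d, c(0.5, -0.2), tolerance = 1e-3)

  # single record, x = 1, omega = 1, kappa = 0, flat prior: N(0, 1)
  flat <- prior_spec(p = 1, flat_beta = TRUE)
  d1 <- replicate(4000, update_beta(1, 0, matrix(1), 0, flat, 1))
  expect_gt(ks.test(d1, pnorm)$p.value, 0.01)
})

test_that("genetic-value update draws from its closed-form normal and shrinks", {
  set.seed(32)
  J <- 3; n <- 12
  line_idx <- rep(1:J, each = 4)
  omega <- runif(n, 0.3, 1.5); kappa <- rnorm(n); eta1 <- rnorm(n, 0, 0.4)
  G1 <- 0.7 * diag(J) + 0.3
  G1inv <- solve(G1)
  s1 <- 0.8
  Z1 <- matrix(0, n, J); Z1[cbind(1:n, line_idx)] <- 1
  F1 <- solve(G1inv / s1 + t(Z1) %*% diag(omega) %*% Z1)
  bt <- F1 %*% (t(Z1) %*% kappa - t(Z1) %*% diag(omega) %*% eta1)
  draws <- t(replicate(5000, update_b1(omega, kappa, eta1, line_idx, G1inv, s1)))
  for (j in 1:J)
    expect_gt(ks.test(draws[, j], pnorm, mean = bt[j],
                      sd = sqrt(F1[j, j]))$p.value, 0.01)
  # sigma_b1^2 -> 0 shrinks the draw to zero
  tiny <- update_b1(omega, kappa, eta1, line_idx, G1inv, 1e-12)
  expect_lt(max(abs(tiny)), 1e-4)
})

test_that("GxE update factorizes over environments with zero cross-covariance", {
  set.seed(33)
  I <- 2; J <- 2; n <- 16
  cell_idx <- rep(1:(I * J), each = 4)
  omega <- runif(n, 0.3, 1.5); kappa <- rnorm(n); eta2 <- rnorm(n, 0, 0.4)
  G1inv <- solve(0.6 * diag(J) + 0.4)
  s2 <- 0.7
  # block-algebra oracle: full IJ-dimensional solve with G2 = I (x) G1
  Z2 <- matrix(0, n, I * J); Z2[cbind(1:n, cell_idx)] <- 1
  G2inv <- kronecker(diag(I), G1inv)
  F2 <- solve(G2inv / s2 + t(Z2) %*% diag(omega) %*% Z2)
  bt <- F2 %*% (t(Z2) %*% kappa - t(Z2) %*% diag(omega) %*% eta2)
  expect_equal(F2[1:J, J + 1:J], matrix(0, J, J), tolerance = 1e-12)
  draws <- t(replicate(5000,
                       update_b2(omega, kappa, eta2, cell_idx, G1inv, s2, I)))
  for (j in 1:(I * J))
    expect_gt(ks.test(draws[, j], pnorm, mean = bt[j],
                      sd = sqrt(F2[j, j]))$p.value, 0.01)
  # empirical covariance across environment blocks is zero
  expect_equal(cov(draws[, 1:J], draws[, J + 1:J]), matrix(0, J, J),
               tolerance = 0.05)
})

test_that("variance update follows the scaled-inv-chi-square conditional", {
  # direct arithmetic: J = 20, nu = 3, S = 0.001, quad = 10
  # -> df 23, scale (10 + 0.003)/23
  set.seed(34)
  draws <- replicate(1e4, update_variance(10, 20, 3, 0.001))
  expect_equal((10 + 0.003) / 23, 0.4349, tolerance = 1e-4)
  expect_gt(ks.test(draws, pinvchisq, nu = 23, S = (10 + 0.003) / 23)$p.value,
            0.01)
  # zero effect vector: scale collapses to nu S / (nu + n)
  d0 <- replicate(5000, update_variance(0, 20, 3, 0.001))
  expect_gt(ks.test(d0, pinvchisq, nu = 23, S = 3 * 0.001 / 23)$p.value, 0.01)
  expect_lt(quantile(d0, 0.99), 0.01)
})

test_that("dispersion update follows its gamma conditional", {
  set.seed(35)
  # single record y = 1, pi = 1/2 (eta* = 0): L = 1 always,
  # r | . ~ Gamma(a0 + 1, rate = b0 + log 2)
  a0 <- 0.01; b0 <- 0.01
  out <- replicate(1e4, update_dispersion(1L, 0, r = 2, a0, b0)$r)
  expect_gt(ks.test(out, pgamma, shape = a0 + 1, rate = b0 + log(2))$p.value,
            0.01)
  # all-zero counts with very negative predictors: L = 0 and the prior is
  # recovered, r ~ Gamma(a0, b0)
  y0 <- rep(0L, 30); eta0 <- rep(-40, 30)
  upd <- update_dispersion(y0, eta0, r = 2, a0 = 2, b0 = 1)
  expect_identical(upd$L, rep(0L, 30))
  out0 <- replicate(1e4, update_dispersion(y0, eta0, r = 2, 2, 1)$r)
  expect_gt(ks.test(out0, pgamma, shape = 2, rate = 1)$p.value, 0.01)
  # near-certain success probabilities stay finite via the logistic log-CDF
  upd_hi <- update_dispersion(c(5L, 7L), c(40, 45), r = 1, a0, b0)
  expect_true(is.finite(upd_hi$r) && upd_hi$r > 0)
})

test_that("PG weight update has the conditional PG moments", {
  set.seed(36)
  # y = 0, r = 1, eta* = 0: PG(1, 0), mean 1/4
  w <- replicate(4000, update_omega(0L, 0, 1))
  expect_lt(abs(mean(w) - 0.25), 4 * sqrt(pg_moments(1, 0)$var / 4000))
  # Model Pois regime: b = y + 1000 stays finite and positive
  w2 <- update_omega(5L, 0.3, 1000)
  expect_true(is.finite(w2) && w2 > 0)
  # exchangeable cells: equal means across identical-count cells
  y <- rep(3L, 4000); eta <- rep(0.5, 4000)
  w3 <- update_omega(y, eta, 2)
  m <- pg_moments(5, 0.5)
  expect_lt(abs(mean(w3) - m$mean), 4 * sqrt(m$var / 4000))
})
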