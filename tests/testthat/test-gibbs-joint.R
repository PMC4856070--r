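# Joint correctness and chain mechanics of the full sampler.

test_that("successive-conditional simulation preserves the prior (Geweke-style)", {
  # Alternating (a) data simulation given the state and (b) one Gibbs sweep
  # leaves the prior distribution of the parameters invariant.  Run a long
  # successive-conditional chain on a tiny model and compare the chain's
  # marginal means with the analytic prior means, using batch-means SEs.
  set.seed(51)
  I <- 2; J <- 3; n_rep <- 2
  panel0 <- toy_panel(I = I, J = J, K = 1, n = n_rep)
  design <- build_design(panel0, include_blocks = FALSE)
  G1 <- diag(J); G1inv <- G1
  # proper, moderately tight priors with finite moments
  prior <- prior_spec(p = I, beta0 = 0, Sigma0 = 0.25,
                      nu_b1 = 10, S_b1 = 0.3, nu_b2 = 10, S_b2 = 0.3,
                      a0 = 10, b0 = 2)
  draw_prior <- function() {
    s1 <- rinvchisq(1, 10, 0.3); s2 <- rinvchisq(1, 10, 0.3)
    list(beta = rnorm(I, 0, 0.5),
         b1 = rnorm(J, 0, sqrt(s1)), b2 = rnorm(I * J, 0, sqrt(s2)),
         s1 = s1, s2 = s2, r = rgamma(1, 10, rate = 2))
  }
  st <- draw_prior()
  M <- 4000
  keep <- matrix(NA_real_, M, 6,
                 dimnames = list(NULL, c("beta1", "beta2", "r", "s1", "s2", "b1sq")))
  li <- design$line_idx; ci <- design$cell_idx; X <- design$X
  for (m in seq_len(M)) {
    eta_star <- drop(X %*% st$beta) + st$b1[li] + st$b2[ci]
    y <- rnbinom(length(eta_star), size = st$r, mu = st$r * exp(eta_star))
    # one Gibbs sweep in the package's order
    upd <- update_dispersion(y, eta_star, st$r, prior$a0, prior$b0)
    st$r <- upd$r
    omega <- update_omega(y, eta_star, st$r)
    kappa <- (y - st$r) / 2
    st$beta <- update_beta(omega, kappa, X, st$b1[li] + st$b2[ci], prior, 1)
    xb <- drop(X %*% st$beta)
    st$b1 <- update_b1(omega, kappa, xb + st$b2[ci], li, G1inv, st$s1)
    st$b2 <- update_b2(omega, kappa, xb + st$b1[li], ci, G1inv, st$s2, I)
    st$s1 <- update_variance(sum(st$b1^2), J, 10, 0.3)
    q2 <- sum(st$b2^2)
    st$s2 <- update_variance(q2, I * J, 10, 0.3)
    keep[m, ] <- c(st$beta, st$r, st$s1, st$s2, mean(st$b1^2))
  }
  # analytic prior means: beta 0, r = 10/2 = 5, sigma^2 = nu S/(nu-2) = 0.375,
  # E[b1^2] = E[sigma1^2] = 0.375
  target <- c(beta1 = 0, beta2 = 0, r = 5, s1 = 0.375, s2 = 0.375,
              b1sq = 0.375)
  batch <- function(x, nb = 40) {
    bm <- colMeans(matrix(x, ncol = nb))
    sd(bm) / sqrt(nb)
  }
  for (parm in colnames(keep)) {
    se <- batch(keep[, parm])
    z <- (mean(keep[, parm]) - target[parm]) / se
    expect_lt(abs(z), 5, label = sprintf("prior invariance of %s (z)", parm))
  }
})

test_that("chains are bit-identical under the same seed", {
  sim <- simulate_panel(sim_config(I = 2, J = 4, K = 0, n = 3,
                                   beta_true = c(1, 0), r_true = 4), seed = 3)
  design <- build_design(sim$panel, include_blocks = FALSE)
  covset <- covariance_set(diag(4), n_env = 2)
  prior <- simulation_priors(p = 2)
  f1 <- run_gibbs(sim$panel, design, covset, prior, 200, 100, seed = 42)
  f2 <- run_gibbs(sim$panel, design, covset, prior, 200, 100, seed = 42)
  expect_identical(f1$chains, f2$chains)
  f3 <- run_gibbs(sim$panel, design, covset, prior, 200, 100, seed = 43)
  expect_false(identical(f1$chains$r, f3$chains$r))
})

test_that("single retained draw and thinning bookkeeping are well-formed", {
  sim <- simulate_panel(sim_config(I = 2, J = 3, K = 0, n = 2,
                                   beta_true = c(0.5, 0), r_true = 3), seed = 5)
  design <- build_design(sim$panel, include_blocks = FALSE)
  covset <- covariance_set(diag(3), n_env = 2)
  prior <- simulation_priors(p = 2)
  f <- run_gibbs(sim$panel, design, covset, prior,
                 iterations = 11, burn_in = 10, seed = 1)
  expect_identical(f$meta$n_kept, 1L)
  expect_identical(nrow(f$chains$beta), 1L)
  expect_true(all(is.finite(f$chains$loglik)))
  fthin <- run_gibbs(sim$panel, design, covset, prior,
                     iterations = 100, burn_in = 20, thin = 4, seed = 1)
  expect_identical(f_len <- length(fthin$chains$r), 20L)
  expect_error(run_gibbs(sim$panel, design, covset, prior, 10, 10),
               "iterations > burn_in")
})

test_that("fixed dispersion (Poisson mode) holds r constant and skips its update", {
  sim <- simulate_panel(sim_config(I = 2, J = 3, K = 0, n = 3,
                                   beta_true = c(1, 0.5), r_true = Inf), seed = 6)
  design <- build_design(sim$panel, include_blocks = FALSE)
  covset <- covariance_set(diag(3), n_env = 2)
  prior <- simulation_priors(p = 2)
  f <- run_gibbs(sim$panel, design, covset, prior, 60, 30,
                 fixed_r = 1000, seed = 2)
  expect_true(all(f$chains$r == 1000))
  # back-transform applies only to the environment entries
  expect_equal(f$chains$beta[, 1], f$chains$beta_star[, 1] + log(1000))
})

test_that("interaction-free model keeps b2 at zero and its variance unsampled", {
  sim <- simulate_panel(sim_config(I = 2, J = 3, K = 0, n = 3,
                                   beta_true = c(1, 0), r_true = 4), seed = 7)
  design <- build_design(sim$panel, include_blocks = FALSE)
  covset <- covariance_set(diag(3), n_env = 2)
  prior <- simulation_priors(p = 2)
  f <- run_gibbs(sim$panel, design, covset, prior, 60, 30,
                 interaction = FALSE, seed = 2)
  expect_true(all(f$chains$b2 == 0))
  expect_true(all(is.na(f$chains$sigma_b2_sq)))
  expect_true(all(is.finite(f$chains$sigma_b1_sq)))
})

test_that("posterior means agree with a brute-force posterior on a tiny model", {
  # One environment, two lines, four replicates; dispersion fixed and the
  # variance pinned by an overwhelming prior, so the unknowns are
  # (beta*, b1_1, b1_2).  The oracle integrates the unaugmented NB likelihood
  # times the priors on a dense grid.
  set.seed(61)
  y <- c(3L, 1L, 4L, 2L, 0L, 1L, 0L, 2L)
  df <- data.frame(env = "E1", block = "B1",
                   line = rep(c("L1", "L2"), each = 4),
                   rep = rep(1:4, 2), count = y)
  panel <- count_panel(df)
  design <- build_design(panel, include_blocks = FALSE)
  covset <- covariance_set(diag(2), n_env = 1)
  r_fix <- 4
  s_fix <- 0.3
  prior <- prior_spec(p = 1, beta0 = 0, Sigma0 = 1,
                      nu_b1 = 1e7, S_b1 = s_fix, nu_b2 = 1e7, S_b2 = s_fix,
                      a0 = 1, b0 = 1)
  fit <- run_gibbs(panel, design, covset, prior,
                   iterations = 12000, burn_in = 2000,
                   fixed_r = r_fix, interaction = FALSE, seed = 99)

  # grid oracle over (beta*, b1_1, b1_2)
  gr <- seq(-3, 3, length.out = 61)
  grid <- expand.grid(beta = gr, b1 = gr, b2 = gr)
  y1 <- y[1:4]; y2 <- y[5:8]
  loglik <- function(eta, yy) {
    vapply(eta, function(e) sum(lgamma(yy + r_fix) - lgamma(yy + 1) -
      lgamma(r_fix) + yy * e - (yy + r_fix) * log1p(exp(e))), numeric(1))
  }
  lp <- loglik(grid$beta + grid$b1, y1) + loglik(grid$beta + grid$b2, y2) +
    dnorm(grid$beta, 0, 1, log = TRUE) +
    dnorm(grid$b1, 0, sqrt(s_fix), log = TRUE) +
    dnorm(grid$b2, 0, sqrt(s_fix), log = TRUE)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  oracle <- c(sum(w * grid$beta), sum(w * grid$b1), sum(w * grid$b2))
  gibbs <- c(mean(fit$chains$beta_star[, 1]), colMeans(fit$chains$b1))
  expect_lt(max(abs(gibbs - oracle)), 0.05)
})
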