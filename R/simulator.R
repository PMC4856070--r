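#' Configure a simulation scenario
#'
#' Describes a multi-environment trial simulated from the model itself:
#' `eta_ij = E_i + g_j + gE_ij` (plus optional block effects), with
#' `g ~ N(0, G1 sigma_b1^2)`, `gE ~ N(0, (I_I (x) G1) sigma_b2^2)` and counts
#' `y ~ NB(mu = exp(eta), r_true)` (Poisson when `r_true = Inf`).
#'
#' @param I,J,K,n environments, lines, blocks (0 = no block effects) and
#'   replicates per cell.
#' @param beta_true environment coefficients (length I).
#' @param block_true optional I*K block coefficients (environment-major);
#'   zeros when `K > 0` and not supplied.
#' @param G1 line covariance: a J-by-J matrix, `"identity"`, or
#'   `"cs"` (compound symmetry, see `rho`).
#' @param rho compound-symmetry correlation when `G1 = "cs"`:
#'   `(1 - rho) I + rho J` (unit diagonal).
#' @param sigma_b1_sq,sigma_b2_sq genetic and GxE variances (>= 0).
#' @param r_true NB dispersion; `Inf` simulates Poisson counts.
#' @return object of class `bmnb_scenario`.
#' @export
sim_config <- function(I = 3, J = 20, K = 0, n = 10,
                       beta_true = c(1.5, -1, 1), block_true = NULL,
                       G1 = "identity", rho = 0.3,
                       sigma_b1_sq = 0.5, sigma_b2_sq = 0.5,
                       r_true = 5) {
  stopifnot(I >= 1, J >= 1, K >= 0, n >= 1,
            sigma_b1_sq >= 0, sigma_b2_sq >= 0, r_true > 0)
  if (length(beta_true) != I) stop("'beta_true' must have length I")
  if (is.character(G1)) {
    G1 <- switch(match.arg(G1, c("identity", "cs")),
                 identity = diag(J),
                 cs = (1 - rho) * diag(J) + rho * matrix(1, J, J))
  } else {
    G1 <- as.matrix(G1)
    if (nrow(G1) != J) stop("'G1' must be J x J")
  }
  if (K > 0) {
    if (is.null(block_true)) block_true <- numeric(I * K)
    if (length(block_true) != I * K) stop("'block_true' must have length I*K")
  }
  structure(list(I = I, J = J, K = K, n = n,
                 beta_true = beta_true, block_true = block_true,
                 G1 = G1, sigma_b1_sq = sigma_b1_sq,
                 sigma_b2_sq = sigma_b2_sq, r_true = r_true),
            class = "bmnb_scenario")
}

#' The two benchmark simulation scenarios
#'
#' Scenario 1: I = 3 environments, J = 20 lines, `G1 = I_20`,
#' `sigma_b1^2 = sigma_b2^2 = 0.5`, `beta = (1.5, -1, 1)`, `r = 5`, no blocks.
#' Scenario 2 is identical except `G1 = 0.7 I_20 + 0.3 J_20`, imitating the
#' correlation between lines seen in real marker data.
#'
#' @param scenario 1 or 2.
#' @param n replicates of each line in each environment (5, 10, 20 or 40 in
#'   the benchmark study; any positive integer accepted).
#' @return object of class `bmnb_scenario`.
#' @export
scenario_config <- function(scenario = 1, n = 10) {
  stopifnot(scenario %in% c(1, 2))
  G1 <- if (scenario == 1) diag(20) else 0.7 * diag(20) + 0.3 * matrix(1, 20, 20)
  sim_config(I = 3, J = 20, K = 0, n = n,
             beta_true = c(1.5, -1, 1), G1 = G1,
             sigma_b1_sq = 0.5, sigma_b2_sq = 0.5, r_true = 5)
}

#' Simulate a count panel from the model
#'
#' Draws the latent genetic and GxE effects, forms `mu = exp(eta)`, and
#' simulates counts NB(mu, r) (Poisson for `r_true = Inf`), i.i.d. over
#' replicates.  The latent truth is returned alongside the data so recovery
#' studies and oracle comparisons can use it.
#'
#' @param config a [sim_config()] / [scenario_config()].
#' @param seed optional integer seed.
#' @return list of class `bmnb_sim` with elements `panel` (a [count_panel()],
#'   rows in canonical order) and `truth` (list: `beta`, `block`, `g`, `gE`
#'   (environment-major), per-record `eta` and `mu`, and the config).
#' @export
simulate_panel <- function(config, seed = NULL) {
  stopifnot(inherits(config, "bmnb_scenario"))
  if (!is.null(seed)) set.seed(seed)
  I <- config$I; J <- config$J; K <- max(config$K, 1L); n <- config$n
  ch <- chol(config$G1)  # errors on non-positive-definite G1
  g <- drop(crossprod(ch, rnorm(J))) * sqrt(config$sigma_b1_sq)
  gE <- as.vector(vapply(seq_len(I), function(i)
    drop(crossprod(ch, rnorm(J))) * sqrt(config$sigma_b2_sq),
    numeric(J)))

  env_lab <- sprintf("E%d", seq_len(I))
  line_lab <- sprintf("L%03d", seq_len(J))
  blk_lab <- sprintf("B%d", seq_len(K))

  grid <- expand.grid(rep = seq_len(n), block = seq_len(K),
                      line = seq_len(J), env = seq_len(I))
  # canonical order: env-major, then line, then block, then replicate
  grid <- grid[order(grid$env, grid$line, grid$block, grid$rep), ]
  eta <- config$beta_true[grid$env] + g[grid$line] +
    gE[(grid$env - 1L) * J + grid$line]
  if (config$K > 0)
    eta <- eta + config$block_true[(grid$env - 1L) * config$K + grid$block]
  mu <- exp(eta)
  y <- if (is.finite(config$r_true))
    rnbinom(length(mu), size = config$r_true, mu = mu)
  else
    rpois(length(mu), lambda = mu)

  df <- data.frame(env = env_lab[grid$env], block = blk_lab[grid$block],
                   line = line_lab[grid$line], rep = grid$rep, count = y,
                   stringsAsFactors = FALSE)
  panel <- count_panel(df)
  structure(list(panel = panel,
                 truth = list(beta = config$beta_true,
                              block = config$block_true,
                              g = g, gE = gE, eta = eta, mu = mu,
                              config = config)),
            class = "bmnb_sim")
}

#' Replicated parameter-recovery study
#'
#' Repeatedly simulates a panel from `config`, fits the mixed
#' negative-binomial model with the simulation-study priors, and tabulates,
#' for each parameter, the average and SD across replications of the
#' per-replication posterior means (the environment coefficients are reported
#' back-transformed, `beta_i = beta*_i + log r`).  A replication whose chain
#' becomes non-finite is flagged (its row is kept as `NA` with a warning),
#' never silently dropped.
#'
#' @param config a [sim_config()] / [scenario_config()].
#' @param replications number of simulated data sets (>= 2).
#' @param iterations,burn_in Gibbs settings per replication.
#' @param seed optional integer seed for the whole study.
#' @param verbose print one line per replication.
#' @return object of class `bmnb_recovery`: `table` (parameter, true, mean,
#'   sd) and `per_rep` (replications-by-parameters matrix of posterior means).
#' @export
run_recovery_study <- function(config, replications = 50,
                               iterations = 20000L, burn_in = 10000L,
                               seed = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "bmnb_scenario"), replications >= 2)
  if (!is.null(seed)) set.seed(seed)
  I <- config$I
  par_names <- c(sprintf("beta%d", seq_len(I) - 1L), "r",
                 "sigma_b1_sq", "sigma_b2_sq")
  true_vals <- c(config$beta_true, config$r_true,
                 config$sigma_b1_sq, config$sigma_b2_sq)
  per_rep <- matrix(NA_real_, replications, length(par_names),
                    dimnames = list(NULL, par_names))
  for (rep_i in seq_len(replications)) {
    sim <- simulate_panel(config)
    design <- build_design(sim$panel, include_blocks = config$K > 0)
    covset <- covariance_set(config$G1, n_env = I)
    prior <- simulation_priors(p = design$p)
    fit <- tryCatch(
      run_gibbs(sim$panel, design, covset, prior,
                iterations = iterations, burn_in = burn_in),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning("replication ", rep_i, " failed: ", conditionMessage(fit))
      next
    }
    per_rep[rep_i, ] <- c(colMeans(fit$chains$beta[, seq_len(I), drop = FALSE]),
                          mean(fit$chains$r),
                          mean(fit$chains$sigma_b1_sq),
                          mean(fit$chains$sigma_b2_sq))
    if (verbose)
      message(sprintf("replication %d/%d done (posterior mean of r: %.2f)",
                      rep_i, replications, per_rep[rep_i, "r"]))
  }
  tab <- data.frame(parameter = par_names, true = true_vals,
                    mean = colMeans(per_rep, na.rm = TRUE),
                    sd = apply(per_rep, 2, sd, na.rm = TRUE),
                    row.names = NULL)
  structure(list(table = tab, per_rep = per_rep,
                 replications = replications,
                 iterations = iterations, burn_in = burn_in),
            class = "bmnb_recovery")
}

#' @export
print.bmnb_recovery <- function(x, ...) {
  cat(sprintf("parameter recovery over %d replications (%d iterations, burn-in %d)\n",
              x$replications, x$iterations, x$burn_in))
  print(x$table, digits = 3, ...)
  invisible(x)
}
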