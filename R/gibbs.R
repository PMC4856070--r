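# Full-conditional updates and the Gibbs loop for the Bayesian mixed
# negative-binomial model.  The likelihood is written in logistic form,
#   Pr(y) = C(y, r) exp(eta*)^y / (1 + exp(eta*))^(y + r),
# with eta* = x'beta* + b1_j + b2_ij and beta*_i = beta_i - log(r) for the
# environment coefficients, so that Polya-Gamma latents omega make the
# location conditionals Gaussian and CRT latents L make the r conditional
# gamma.

log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  mid <- x > 18 & x <= 33.3
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

#' Negative-binomial log-pmf in logistic form
#'
#' Log of `Gamma(y + r) / (y! Gamma(r)) * exp(eta*)^y / (1 + exp(eta*))^(y+r)`,
#' the NB(mu, r) log-pmf with `mu = r exp(eta*)` (success probability
#' `pi = mu / (r + mu)`).  Overflow-safe through log-gamma and a stable
#' `log(1 + exp(x))`.
#'
#' @param y non-negative integer count(s).
#' @param eta_star linear predictor on the shifted (logistic) scale.
#' @param r positive dispersion.
#' @return numeric vector of log-probabilities.
#' @export
nb_log_pmf <- function(y, eta_star, r) {
  if (any(y < 0) || any(y != round(y))) stop("'y' must be non-negative integers")
  if (any(r <= 0)) stop("'r' must be positive")
  lgamma(y + r) - lgamma(y + 1) - lgamma(r) +
    y * eta_star - (y + r) * log1pexp(eta_star)
}

#' Draw from a scaled inverse chi-square distribution
#'
#' `X = nu * S / chi^2_nu`, the conjugate conditional family of the model's
#' variance components.
#'
#' @param n number of draws.
#' @param nu degrees of freedom (> 0).
#' @param S scale (> 0).
#' @return numeric vector of positive draws.
#' @export
rinvchisq <- function(n, nu, S) {
  stopifnot(nu > 0, S > 0)
  nu * S / rchisq(n, df = nu)
}

# draw x ~ N(prec^{-1} rhs, prec^{-1}) from precision and linear shift
draw_mvn_prec <- function(prec, rhs) {
  ch <- chol(prec)
  mu <- backsolve(ch, forwardsolve(t(ch), rhs))
  drop(mu + backsolve(ch, rnorm(length(rhs))))
}

#' Update the Polya-Gamma latent weights
#'
#' Each record's weight is drawn from `PG(y + r, eta*)`, its full
#' conditional given the current state.
#'
#' @param y vector of counts.
#' @param eta_star current shifted linear predictor per record.
#' @param r current dispersion (scalar).
#' @return vector of positive PG draws, one per record.
#' @export
update_omega <- function(y, eta_star, r) {
  rpg(length(y), b = y + r, c = eta_star)
}

#' Update the CRT latents and the dispersion
#'
#' Draws the latent table counts `L ~ CRT(y, r)` and then the dispersion from
#' its gamma full conditional, `r ~ Gamma(a0 + sum(L),
#' rate = b0 - sum(log(1 - pi)))` with `pi = exp(eta*) / (1 + exp(eta*))`.
#' `log(1 - pi)` is evaluated through the logistic log-CDF, so records with
#' large predictors cannot produce `log(0)`.
#'
#' @param y counts.
#' @param eta_star shifted linear predictor per record.
#' @param r current dispersion (drives the CRT draws).
#' @param a0,b0 gamma prior shape and rate for `r`.
#' @return list with elements `L` (integer vector) and `r` (new scalar draw).
#' @export
update_dispersion <- function(y, eta_star, r, a0, b0) {
  L <- rcrt(y, r)
  log1mpi <- plogis(eta_star, lower.tail = FALSE, log.p = TRUE)
  list(L = L,
       r = rgamma(1, shape = a0 + sum(L), rate = b0 - sum(log1mpi)))
}

#' Update the fixed effects
#'
#' Gaussian full conditional of `beta*`: precision
#' `Sigma0^{-1}/sigma_beta^2 + X' D_omega X`, shift
#' `Sigma0^{-1} beta0 / sigma_beta^2 + X'(kappa - D_omega (Z1 b1 + Z2 b2))`,
#' with `kappa = (y - r) / 2`.  Under a flat prior the `Sigma0^{-1}` terms are
#' dropped.
#'
#' @param omega PG weights per record.
#' @param kappa `(y - r) / 2` per record.
#' @param X fixed-effect design matrix.
#' @param zb current random-effect contribution `Z1 b1 + Z2 b2` per record.
#' @param prior a [prior_spec()].
#' @param sigma_beta2 current fixed-effect variance scale.
#' @return new draw of `beta*` (length p).
#' @export
update_beta <- function(omega, kappa, X, zb, prior, sigma_beta2 = 1) {
  prec <- crossprod(X, omega * X)
  rhs <- crossprod(X, kappa - omega * zb)
  if (!prior$flat_beta) {
    prec <- prec + prior$Sigma0inv / sigma_beta2
    rhs <- rhs + prior$Sigma0inv %*% prior$beta0 / sigma_beta2
  }
  draw_mvn_prec(prec, rhs)
}

#' Update the genetic values
#'
#' Gaussian full conditional of `b1`: precision
#' `G1^{-1}/sigma_b1^2 + Z1' D_omega Z1` (the second term is diagonal with the
#' per-line sums of omega), shift `Z1'(kappa - D_omega eta1)` with
#' `eta1 = X beta* + Z2 b2`.
#'
#' @param omega,kappa per-record vectors as in [update_beta()].
#' @param eta1 per-record `X beta* + Z2 b2`.
#' @param line_idx 1-based line index per record.
#' @param G1inv inverse of the line covariance.
#' @param sigma_b1_sq current genetic variance.
#' @return new draw of `b1` (length J).
#' @export
update_b1 <- function(omega, kappa, eta1, line_idx, G1inv, sigma_b1_sq) {
  J <- nrow(G1inv)
  d <- .group_sum_cpp(omega, line_idx, J)
  rhs <- .group_sum_cpp(kappa - omega * eta1, line_idx, J)
  prec <- G1inv / sigma_b1_sq
  diag(prec) <- diag(prec) + d
  draw_mvn_prec(prec, rhs)
}

#' Update the GxE effects
#'
#' Gaussian full conditional of `b2` with
#' `eta2 = X beta* + Z1 b1`.  Because `G2 = I_I (x) G1` and `Z2' D_omega Z2`
#' is diagonal, the IJ-dimensional draw factorizes into I independent
#' J-dimensional solves, one per environment.
#'
#' @param omega,kappa per-record vectors.
#' @param eta2 per-record `X beta* + Z1 b1`.
#' @param cell_idx 1-based environment-major cell index per record.
#' @param G1inv inverse line covariance (shared across environments).
#' @param sigma_b2_sq current GxE variance.
#' @param n_env number of environments I.
#' @return new draw of `b2` (length IJ, environment-major).
#' @export
update_b2 <- function(omega, kappa, eta2, cell_idx, G1inv, sigma_b2_sq, n_env) {
  J <- nrow(G1inv)
  d <- .group_sum_cpp(omega, cell_idx, n_env * J)
  rhs <- .group_sum_cpp(kappa - omega * eta2, cell_idx, n_env * J)
  b2 <- numeric(n_env * J)
  for (i in seq_len(n_env)) {
    idx <- (i - 1L) * J + seq_len(J)
    prec <- G1inv / sigma_b2_sq
    diag(prec) <- diag(prec) + d[idx]
    b2[idx] <- draw_mvn_prec(prec, rhs[idx])
  }
  b2
}

#' Update a variance component
#'
#' Scaled-inverse-chi-square full conditional with degrees of freedom
#' `nu + n_b` and scale `(quad + nu S) / (nu + n_b)`, where `quad` is the
#' prior quadratic form `b' G^{-1} b` of the corresponding random effect.
#'
#' @param quad quadratic form of the current effect vector.
#' @param n_b length of the effect vector (J for genetics, IJ for GxE).
#' @param nu,S prior degrees of freedom and scale.
#' @return positive scalar draw.
#' @export
update_variance <- function(quad, n_b, nu, S) {
  df <- nu + n_b
  rinvchisq(1, df, (quad + nu * S) / df)
}

#' Run the Gibbs sampler for the mixed negative-binomial model
#'
#' Executes the augmented sampling loop: CRT latents and dispersion `r`
#' (skipped when `fixed_r` is supplied -- the Poisson special case);
#' Polya-Gamma weights; fixed effects `beta*`; genetic values `b1`; GxE
#' effects `b2`; variance components; optionally `sigma_beta^2`.  The
#' dispersion is updated from its omega-collapsed conditional, so the
#' Polya-Gamma weights are always drawn immediately after `r` (a valid
#' partially collapsed ordering); see the methods vignette for why the
#' weights must never be carried across a dispersion update.  Retained draws
#' store both
#' `beta*` and the back-transformed environment coefficients
#' `beta_i = beta*_i + log(r)` (block coefficients are not shifted), plus the
#' per-draw log-likelihood.
#'
#' @param panel a [count_panel()].
#' @param design a [build_design()] for the same panel.
#' @param covset a [covariance_set()].
#' @param prior a [prior_spec()] with `p = design$p`.
#' @param iterations total Gibbs iterations.
#' @param burn_in iterations discarded (`iterations > burn_in >= 0`).
#' @param fixed_r if supplied, the dispersion is held at this value and its
#'   update is skipped (Model Pois; see [auto_fix_r()]).
#' @param interaction include the GxE term? If `FALSE`, `b2` is fixed at zero
#'   and its variance is not sampled.
#' @param thin keep every `thin`-th post-burn-in draw (default 1: the chains
#'   are not thinned).
#' @param seed optional integer; if given, `set.seed(seed)` is called so the
#'   whole run is reproducible from this one seed.  Otherwise the current RNG
#'   stream is used.
#' @param verbose print progress every 500 iterations.
#' @return object of class `bmnb_fit` with elements `chains` (matrices
#'   `beta_star`, `beta`, `b1`, `b2`, vectors `r`, `sigma_b1_sq`,
#'   `sigma_b2_sq`, `sigma_beta_sq`, `loglik`) and `meta` (run manifest).
#' @export
run_gibbs <- function(panel, design, covset, prior,
                      iterations = 60000L, burn_in = 30000L,
                      fixed_r = NULL, interaction = TRUE,
                      thin = 1L, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(panel, "bmnb_panel"), inherits(design, "bmnb_design"),
            inherits(covset, "bmnb_covset"), inherits(prior, "bmnb_prior"))
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (iterations <= burn_in || burn_in < 0) stop("need iterations > burn_in >= 0")
  if (prior$p != design$p)
    stop("prior has p = ", prior$p, " but design has p = ", design$p)
  if (nrow(covset$G1) != design$J)
    stop("G1 dimension does not match the number of lines")
  if (!is.null(fixed_r) && (!is.finite(fixed_r) || fixed_r <= 0))
    stop("'fixed_r' must be positive")
  if (!is.null(seed)) set.seed(seed)

  y <- panel$count
  n_T <- design$n_T; I <- design$I; J <- design$J; p <- design$p
  X <- design$X
  line_idx <- design$line_idx; cell_idx <- design$cell_idx
  G1inv <- covset$G1inv

  # initial state
  r <- if (is.null(fixed_r)) 1 else fixed_r
  beta_star <- numeric(p)
  b1 <- numeric(J)
  b2 <- numeric(I * J)
  sigma_b1_sq <- 1; sigma_b2_sq <- 1; sigma_beta2 <- 1
  sample_sigma_beta <- !is.null(prior$nu_beta) && !prior$flat_beta

  n_keep <- (iterations - burn_in) %/% thin
  ch_beta_star <- matrix(NA_real_, n_keep, p,
                         dimnames = list(NULL, colnames(X)))
  ch_beta <- ch_beta_star
  ch_b1 <- matrix(NA_real_, n_keep, J, dimnames = list(NULL, colnames(design$Z1)))
  ch_b2 <- matrix(NA_real_, n_keep, I * J,
                  dimnames = list(NULL, colnames(design$Z2)))
  ch_r <- ch_s1 <- ch_s2 <- ch_sb <- ch_ll <- numeric(n_keep)

  env_cols <- seq_len(design$n_env_cols)
  kept <- 0L
  for (it in seq_len(iterations)) {
    eta_star <- drop(X %*% beta_star) + b1[line_idx] +
      (if (interaction) b2[cell_idx] else 0)

    # 1-2. CRT latents and dispersion (skipped under fixed r).  The gamma
    # conditional for r is derived with omega integrated out, so omega must
    # be (re)drawn only after r: carrying an omega drawn under the old r into
    # the location updates breaks the partially collapsed sampler's
    # invariance and destabilizes the r chain.
    if (is.null(fixed_r)) {
      upd <- update_dispersion(y, eta_star, r, prior$a0, prior$b0)
      r <- upd$r
    }

    # 3. Polya-Gamma weights given the fresh dispersion
    omega <- update_omega(y, eta_star, r)
    kappa <- (y - r) / 2

    # 4. fixed effects
    zb <- b1[line_idx] + (if (interaction) b2[cell_idx] else 0)
    beta_star <- update_beta(omega, kappa, X, zb, prior, sigma_beta2)
    xb <- drop(X %*% beta_star)

    # 5. genetic values
    eta1 <- xb + (if (interaction) b2[cell_idx] else 0)
    b1 <- update_b1(omega, kappa, eta1, line_idx, G1inv, sigma_b1_sq)

    # 6. GxE effects
    if (interaction) {
      eta2 <- xb + b1[line_idx]
      b2 <- update_b2(omega, kappa, eta2, cell_idx, G1inv, sigma_b2_sq, I)
    }

    # 7. variance components
    sigma_b1_sq <- update_variance(drop(crossprod(b1, G1inv %*% b1)), J,
                                   prior$nu_b1, prior$S_b1)
    if (interaction) {
      quad2 <- 0
      for (i in seq_len(I)) {
        bi <- b2[(i - 1L) * J + seq_len(J)]
        quad2 <- quad2 + drop(crossprod(bi, G1inv %*% bi))
      }
      sigma_b2_sq <- update_variance(quad2, I * J, prior$nu_b2, prior$S_b2)
    }

    # 8. fixed-effect variance scale (only with an explicit nu_beta, S_beta)
    if (sample_sigma_beta) {
      resid <- beta_star - prior$beta0
      quadb <- drop(crossprod(resid, prior$Sigma0inv %*% resid))
      df <- prior$nu_beta + p
      sigma_beta2 <- rinvchisq(1, df, (quadb + prior$nu_beta * prior$S_beta) / df)
    }

    if (!is.finite(r) || anyNA(beta_star) || any(!is.finite(b1)))
      stop("non-finite state at iteration ", it,
           " (r = ", format(r), "); check data scaling and priors")

    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      eta_cur <- xb + b1[line_idx] + (if (interaction) b2[cell_idx] else 0)
      ch_beta_star[kept, ] <- beta_star
      bt <- beta_star
      bt[env_cols] <- bt[env_cols] + log(r)
      ch_beta[kept, ] <- bt
      ch_b1[kept, ] <- b1
      ch_b2[kept, ] <- b2
      ch_r[kept] <- r
      ch_s1[kept] <- sigma_b1_sq
      ch_s2[kept] <- if (interaction) sigma_b2_sq else NA_real_
      ch_sb[kept] <- sigma_beta2
      ch_ll[kept] <- sum(nb_log_pmf(y, eta_cur, r))
    }
    if (verbose && it %% 500L == 0L)
      message(sprintf("iter %d/%d  r = %.3f  sigma_b1^2 = %.3f  sigma_b2^2 = %.3f",
                      it, iterations, r, sigma_b1_sq, sigma_b2_sq))
  }

  structure(list(
    chains = list(beta_star = ch_beta_star, beta = ch_beta,
                  b1 = ch_b1, b2 = ch_b2, r = ch_r,
                  sigma_b1_sq = ch_s1, sigma_b2_sq = ch_s2,
                  sigma_beta_sq = ch_sb, loglik = ch_ll),
    meta = list(iterations = iterations, burn_in = burn_in, thin = thin,
                n_kept = kept, seed = seed, fixed_r = fixed_r,
                interaction = interaction,
                I = I, J = J, K = design$K, p = p, n_T = n_T,
                include_blocks = design$include_blocks,
                n_env_cols = design$n_env_cols,
                env_levels = attr(panel, "env_levels"),
                line_levels = attr(panel, "line_levels"),
                block_levels = attr(panel, "block_levels"),
                x_colnames = colnames(X),
                prior = prior)),
    class = "bmnb_fit")
}

#' @export
print.bmnb_fit <- function(x, ...) {
  m <- x$meta
  cat(sprintf("bmnb fit: %d retained draws (of %d iterations, burn-in %d)\n",
              m$n_kept, m$iterations, m$burn_in))
  cat(sprintf("  %d environments x %d lines, %d records; GxE %s; r %s\n",
              m$I, m$J, m$n_T,
              if (m$interaction) "included" else "excluded",
              if (is.null(m$fixed_r)) "sampled" else paste("fixed at", m$fixed_r)))
  print(summary(x), ...)
  invisible(x)
}

#' Posterior summary of the scalar parameters
#'
#' @param object a `bmnb_fit`.
#' @param ... unused.
#' @return data.frame of posterior means and SDs for the back-transformed
#'   fixed effects, dispersion and variance components.
#' @export
summary.bmnb_fit <- function(object, ...) {
  ch <- object$chains
  scalars <- cbind(ch$beta, r = ch$r,
                   sigma_b1_sq = ch$sigma_b1_sq,
                   sigma_b2_sq = ch$sigma_b2_sq)
  data.frame(parameter = colnames(scalars),
             mean = colMeans(scalars),
             sd = apply(scalars, 2, sd),
             row.names = NULL)
}

#' Fit the mixed negative-binomial model from a panel and markers
#'
#' Convenience wrapper around [run_gibbs()]: builds the design, forms the
#' line covariance (GRM from markers via [compute_grm()], or an identity for
#' marker-free i.i.d. line effects), chooses a default prior, and -- for the
#' Poisson special case -- fixes the dispersion with [auto_fix_r()] based on
#' the observed mean count.
#'
#' @param panel a [count_panel()] (or a data.frame coercible to one).
#' @param markers optional lines-by-markers 0/1 matrix with rownames matching
#'   the panel's line labels.
#' @param model `"nb"` (dispersion sampled) or `"pois"` (dispersion fixed
#'   large).
#' @param include_blocks model block-within-environment effects?
#' @param interaction include the GxE term?
#' @param prior optional [prior_spec()]; default `prior_spec(p)` with the
#'   weakly informative real-data settings.
#' @param iterations,burn_in,thin,seed,verbose passed to [run_gibbs()].
#' @param fixed_r optional explicit dispersion for `model = "pois"`.
#' @return a `bmnb_fit`.
#' @export
bmnb_fit <- function(panel, markers = NULL, model = c("nb", "pois"),
                     include_blocks = TRUE, interaction = TRUE,
                     prior = NULL,
                     iterations = 60000L, burn_in = 30000L, thin = 1L,
                     fixed_r = NULL, seed = NULL, verbose = FALSE) {
  model <- match.arg(model)
  if (!inherits(panel, "bmnb_panel")) panel <- count_panel(panel)
  design <- build_design(panel, include_blocks = include_blocks)
  J <- design$J
  if (is.null(markers)) {
    G1 <- diag(J)
  } else {
    markers <- as.matrix(markers)
    if (is.null(rownames(markers)))
      stop("'markers' must have line labels as rownames")
    miss <- setdiff(attr(panel, "line_levels"), rownames(markers))
    if (length(miss))
      stop("no marker row for line(s): ", paste(utils::head(miss, 5), collapse = ", "))
    G1 <- compute_grm(markers[attr(panel, "line_levels"), , drop = FALSE])
  }
  covset <- covariance_set(G1, n_env = design$I)
  if (is.null(prior)) prior <- prior_spec(p = design$p)
  if (model == "pois" && is.null(fixed_r)) fixed_r <- auto_fix_r(mean(panel$count))
  if (model == "nb") fixed_r <- NULL
  run_gibbs(panel, design, covset, prior,
            iterations = iterations, burn_in = burn_in,
            fixed_r = fixed_r, interaction = interaction,
            thin = thin, seed = seed, verbose = verbose)
}
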