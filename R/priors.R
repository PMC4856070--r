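#' Prior specification for the mixed negative-binomial model
#'
#' Conditionally conjugate, weakly informative priors:
#' `beta* | sigma_beta^2 ~ N_p(beta0, Sigma0 sigma_beta^2)`,
#' `sigma_bh^2 ~ scaled-inv-chi^2(nu_bh, S_bh)` for the genetic (h = 1) and
#' GxE (h = 2) variance components, and `r ~ Gamma(a0, scale = 1/b0)` for the
#' dispersion.
#'
#' By default `sigma_beta^2` is held fixed at 1 (the fixed-effect prior is
#' then simply `N(beta0, Sigma0)`, the standard real-data setting with
#' `Sigma0 = 10^4 I`); supplying both `nu_beta` and `S_beta` turns on the
#' scaled-inverse-chi-square update for `sigma_beta^2`.  Setting
#' `flat_beta = TRUE` drops the fixed-effect prior precision entirely
#' (improper flat prior); the design must then be full column rank
#' (see `drop_last_block` in [build_design()]).
#'
#' @param p number of fixed-effect columns (used to expand scalar `beta0` /
#'   `Sigma0`); may be `NULL` if both are given as full vector/matrix.
#' @param beta0 prior mean vector (scalar recycled).
#' @param Sigma0 prior covariance scale: scalar (times identity), vector
#'   (diagonal) or full p-by-p matrix.
#' @param nu_b1,S_b1 shape and scale of the scaled-inv-chi^2 prior for the
#'   genetic variance.
#' @param nu_b2,S_b2 same for the GxE variance.
#' @param a0,b0 gamma prior shape and rate for the dispersion `r`.
#' @param nu_beta,S_beta optional scaled-inv-chi^2 prior for `sigma_beta^2`;
#'   both `NULL` (default) fixes `sigma_beta^2 = 1`.
#' @param flat_beta use an improper flat prior on `beta*`.
#' @return object of class `bmnb_prior`.
#' @export
prior_spec <- function(p = NULL,
                       beta0 = 0, Sigma0 = 1e4,
                       nu_b1 = 3, S_b1 = 0.001,
                       nu_b2 = 3, S_b2 = 0.001,
                       a0 = 0.01, b0 = 0.01,
                       nu_beta = NULL, S_beta = NULL,
                       flat_beta = FALSE) {
  if (is.null(p)) {
    if (is.matrix(Sigma0)) p <- nrow(Sigma0)
    else p <- max(length(beta0), length(Sigma0))
  }
  beta0 <- rep_len(as.numeric(beta0), p)
  if (is.matrix(Sigma0)) {
    stopifnot(nrow(Sigma0) == p, ncol(Sigma0) == p)
  } else {
    Sigma0 <- diag(rep_len(as.numeric(Sigma0), p), p)
  }
  stopifnot(nu_b1 > 0, S_b1 > 0, nu_b2 > 0, S_b2 > 0, a0 > 0, b0 > 0)
  if (xor(is.null(nu_beta), is.null(S_beta)))
    stop("supply both 'nu_beta' and 'S_beta', or neither")
  if (!flat_beta && inherits(tryCatch(chol(Sigma0), error = identity), "error"))
    stop("'Sigma0' must be positive definite")
  structure(list(p = p, beta0 = beta0, Sigma0 = Sigma0,
                 Sigma0inv = if (flat_beta) NULL else chol2inv(chol(Sigma0)),
                 nu_b1 = nu_b1, S_b1 = S_b1, nu_b2 = nu_b2, S_b2 = S_b2,
                 a0 = a0, b0 = b0,
                 nu_beta = nu_beta, S_beta = S_beta,
                 flat_beta = flat_beta),
            class = "bmnb_prior")
}

#' Simulation-study priors
#'
#' The approximately flat priors used for the simulation scenarios:
#' `beta* ~ N(0, 10^4 I_p)`, `r ~ Gamma(0.001, scale = 1/0.001)` and
#' `sigma_bh^2 ~ scaled-inv-chi^2(0.50002, 4.0002)` for both variance
#' components.
#'
#' @param p number of fixed-effect columns (3 environments by default).
#' @return object of class `bmnb_prior`.
#' @export
simulation_priors <- function(p = 3) {
  prior_spec(p = p, beta0 = 0, Sigma0 = 1e4,
             nu_b1 = 0.50002, S_b1 = 4.0002,
             nu_b2 = 0.50002, S_b2 = 4.0002,
             a0 = 0.001, b0 = 0.001)
}
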