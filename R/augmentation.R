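#' Draw Polya-Gamma random variates
#'
#' Samples from the Polya-Gamma distribution PG(b, c), the latent-variable
#' distribution that renders the location conditionals of a logistic-form
#' negative-binomial likelihood Gaussian.  The shape `b` may be any positive
#' real (in the Gibbs sampler `b = y + r` with continuous dispersion `r`).
#'
#' A hybrid sampler is used: the integer part of `b` is drawn as a sum of
#' exact Devroye-type PG(1, c) variates; the fractional part uses the infinite
#' gamma-convolution representation truncated after 16 terms with the dropped
#' tail replaced by a gamma variate matching the tail's exact mean and
#' variance; for `b > 170` a moment-matched normal is used (CLT regime,
#' relevant to the Poisson special case where `b = y + 1000`).  All draws use
#' R's RNG, so results are reproducible under [set.seed()].
#'
#' @param n number of draws.
#' @param b shape parameter(s), positive real, recycled to length `n`.
#' @param c tilt parameter(s), finite real, recycled to length `n`.
#' @return numeric vector of `n` positive draws.
#' @examples
#' set.seed(1)
#' mean(rpg(1e4, b = 1, c = 0))   # ~ 1/4
#' @seealso [pg_moments()] for the closed-form mean and variance.
#' @export
rpg <- function(n, b, c = 0) {
  n <- as.integer(n)
  stopifnot(n >= 0)
  b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n)
  if (any(!is.finite(b)) || any(b <= 0))
    stop("'b' must be positive and finite")
  if (any(!is.finite(c)))
    stop("'c' must be finite")
  .rpg_cpp(b, c)
}

#' Closed-form Polya-Gamma moments
#'
#' Mean `(b / 2c) tanh(c / 2)` (limit `b/4` at `c = 0`) and variance
#' `(b / 4c^3) (sinh(c) - c) sech^2(c / 2)` (limit `b/24`) of PG(b, c).
#'
#' @param b,c PG parameters, recycled to a common length.
#' @return data.frame with columns `mean` and `var`.
#' @export
pg_moments <- function(b, c = 0) {
  len <- max(length(b), length(c))
  b <- rep_len(as.numeric(b), len)
  c <- rep_len(as.numeric(c), len)
  m <- .pg_moments_cpp(b, c)
  data.frame(mean = m[, 1], var = m[, 2])
}

#' Draw Chinese-restaurant-table counts
#'
#' Samples the latent table count L ~ CRT(y, r), the sum of `y` independent
#' Bernoulli(r / (l - 1 + r)) indicators, l = 1, ..., y.  In the Gibbs sampler
#' these latents make the conditional of the NB dispersion `r` a gamma
#' distribution.  The naive Bernoulli summation is kept for transparency
#' (counts here are at most a few hundred); a gamma-rate approximation exists
#' for very large counts but is not used.
#'
#' @param y non-negative integer count(s).
#' @param r positive dispersion, recycled to the length of `y`.
#' @return integer vector of table counts in `[min(1, y), y]`;
#'   `L = 0` iff `y = 0`.
#' @examples
#' set.seed(1)
#' rcrt(c(0, 1, 5), r = 2)
#' @export
rcrt <- function(y, r) {
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y)))
    stop("'y' must be non-negative integers")
  r <- rep_len(as.numeric(r), length(y))
  if (any(!is.finite(r)) || any(r <= 0))
    stop("'r' must be positive and finite")
  .rcrt_cpp(as.integer(round(y)), r)
}

#' Expected Chinese-restaurant-table count
#'
#' `E[CRT(y, r)] = r (digamma(r + y) - digamma(r))`.
#'
#' @param y non-negative integer count(s).
#' @param r positive dispersion.
#' @return numeric vector of expectations.
#' @export
crt_mean <- function(y, r) {
  r * (digamma(r + y) - digamma(r))
}
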