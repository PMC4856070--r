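// Samplers for the two latent-variable distributions the Gibbs sampler needs:
// Polya-Gamma PG(b, c) and the Chinese-restaurant-table count CRT(y, r).
//
// PG(b, c) is drawn by a hybrid scheme:
//   * integer part of b: sum of exact Devroye-type PG(1, c) draws
//     (Devroye 2009; Polson, Scott & Windle 2013, alternating-series rejection);
//   * fractional part in (0, 1): truncated infinite gamma convolution
//     PG(b, c) = (1 / 2 pi^2) * sum_k Gamma(b, 1) / ((k - 1/2)^2 + c^2 / (4 pi^2))
//     with the dropped tail replaced by a gamma variate matching the tail's
//     exact mean and variance;
//   * b > 170: moment-matched normal (CLT regime; used by Model Pois where
//     b = y + 1000).
// All randomness comes from R's RNG so set.seed() governs every draw.

#include <Rcpp.h>
using namespace Rcpp;

static const double TRUNC = 0.64;             // series change-over point
static const double PISQ  = M_PI * M_PI;

// mean of PG(b, c): (b / 2c) tanh(c / 2), limit b/4 at c = 0
static double pg_mean_d(double b, double c) {
  double ac = std::fabs(c);
  if (ac < 1e-6) return b * (0.25 - ac * ac / 48.0);
  return b / (2.0 * c) * std::tanh(0.5 * c);
}

// variance of PG(b, c): (b / 4c^3) (sinh c - c) sech^2(c / 2), limit b/24
static double pg_var_d(double b, double c) {
  double ac = std::fabs(c);
  if (ac < 1e-3) return b / 24.0;
  if (ac > 30.0) {
    // (sinh c - c) sech^2(c/2) -> 2 - 4 c e^{-c}; avoids sinh/cosh overflow
    return b * (2.0 - 4.0 * ac * std::exp(-ac)) / (4.0 * ac * ac * ac);
  }
  double sech_half = 1.0 / std::cosh(0.5 * ac);
  return b * (std::sinh(ac) - ac) / (4.0 * ac * ac * ac) * sech_half * sech_half;
}

// one inverse-Gaussian(mu, lambda = 1) draw (Michael-Schucany-Haas)
static double rinvgauss1(double mu) {
  double v = norm_rand();
  double y = v * v;
  double x = mu + 0.5 * mu * mu * y -
             0.5 * mu * std::sqrt(4.0 * mu * y + mu * mu * y * y);
  if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
  return x;
}

// IG(1/z, 1) truncated to (0, TRUNC); z >= 0
static double rtinvgauss(double z) {
  double t = TRUNC, x;
  if (z < 1.0 / t) {
    // mu > t: rejection via truncated inverse-chi-square with exp tilt
    for (;;) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (std::log(unif_rand()) <= -0.5 * z * z * x) return x;
    }
  } else {
    double mu = 1.0 / z;
    do {
      x = rinvgauss1(mu);
    } while (x >= t);
    return x;
  }
}

// alternating-series coefficients a_n(x) of the J*(1, 0) density
static double a_coef(int n, double x) {
  double npd = n + 0.5;
  if (x > TRUNC)
    return M_PI * npd * std::exp(-0.5 * npd * npd * PISQ * x);
  return std::pow(2.0 / (M_PI * x), 1.5) * M_PI * npd *
         std::exp(-2.0 * npd * npd / x);
}

// probability of proposing from the truncated-exponential (x > TRUNC) branch
static double mass_texpon(double z) {
  double t = TRUNC;
  double k = 0.125 * PISQ + 0.5 * z * z;
  double b = std::sqrt(1.0 / t) * (t * z - 1.0);
  double a = -std::sqrt(1.0 / t) * (t * z + 1.0);
  double x0 = std::log(k) + k * t;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// exact PG(1, c) draw, Devroye-type rejection; z = |c|/2 and the proposal
// constants are hoisted so repeated draws at the same tilt share them
static double rpg1_pre(double z, double k, double p_texp) {
  for (;;) {
    double x;
    if (unif_rand() < p_texp)
      x = TRUNC + exp_rand() / k;
    else
      x = rtinvgauss(z);
    // squeeze on the alternating series
    double s = a_coef(0, x);
    double y = unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return 0.25 * x;   // accept
      } else {
        s += a_coef(n, x);
        if (y > s) break;              // reject, new proposal
      }
    }
  }
}

// PG(b, c) for 0 < b < 1 via truncated gamma convolution + matched gamma tail
static double rpg_frac(double b, double c, int nterms) {
  double c2 = 0.25 * c * c / PISQ;
  double x = 0.0, sumw = 0.0, sumw2 = 0.0;
  for (int kk = 1; kk <= nterms; ++kk) {
    double d = (kk - 0.5) * (kk - 0.5) + c2;
    double w = 1.0 / (2.0 * PISQ * d);
    x += w * R::rgamma(b, 1.0);
    sumw += w;
    sumw2 += w * w;
  }
  // exact tail weight sums via the closed-form PG(1, c) moments
  double m = b * (pg_mean_d(1.0, c) - sumw);
  double v = b * (pg_var_d(1.0, c) - sumw2);
  if (m > 0.0 && v > 0.0) x += R::rgamma(m * m / v, v / m);
  return x;
}

static double rpg_one(double b, double c) {
  if (b > 170.0) {
    // CLT regime: moment-matched normal
    double m = pg_mean_d(b, c), s = std::sqrt(pg_var_d(b, c));
    double x = m + s * norm_rand();
    return (x > 1e-12) ? x : 1e-12;
  }
  double x = 0.0;
  int n_int = (int)std::floor(b);
  double frac = b - n_int;
  if (n_int > 0) {
    double z = 0.5 * std::fabs(c);
    double k = 0.125 * PISQ + 0.5 * z * z;
    double p_texp = mass_texpon(z);
    for (int i = 0; i < n_int; ++i) x += rpg1_pre(z, k, p_texp);
  }
  if (frac > 1e-12) x += rpg_frac(frac, c, 12);
  return x;
}

// [[Rcpp::export(name = ".rpg_cpp")]]
NumericVector rpg_cpp(NumericVector b, NumericVector c) {
  R_xlen_t n = b.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!(b[i] > 0.0) || !R_FINITE(b[i]))
      stop("PG shape parameter 'b' must be positive and finite");
    if (!R_FINITE(c[i]))
      stop("PG tilt parameter 'c' must be finite");
    out[i] = rpg_one(b[i], c[i]);
  }
  return out;
}

// [[Rcpp::export(name = ".pg_moments_cpp")]]
NumericMatrix pg_moments_cpp(NumericVector b, NumericVector c) {
  R_xlen_t n = b.size();
  NumericMatrix out(n, 2);
  for (R_xlen_t i = 0; i < n; ++i) {
    out(i, 0) = pg_mean_d(b[i], c[i]);
    out(i, 1) = pg_var_d(b[i], c[i]);
  }
  return out;
}

// CRT(y, r) = sum_{l=1}^{y} Bernoulli(r / (l - 1 + r))
// [[Rcpp::export(name = ".rcrt_cpp")]]
IntegerVector rcrt_cpp(IntegerVector y, NumericVector r) {
  R_xlen_t n = y.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (y[i] == NA_INTEGER || y[i] < 0)
      stop("CRT count 'y' must be a non-negative integer");
    if (!(r[i] > 0.0) || !R_FINITE(r[i]))
      stop("CRT rate 'r' must be positive and finite");
    int L = 0;
    for (int l = 1; l <= y[i]; ++l)
      if (unif_rand() < r[i] / (l - 1.0 + r[i])) ++L;
    out[i] = L;
  }
  return out;
}

// group sums: sum x over records sharing a 1-based group index
// [[Rcpp::export(name = ".group_sum_cpp")]]
NumericVector group_sum_cpp(NumericVector x, IntegerVector idx, int ngroups) {
  NumericVector out(ngroups);
  R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    int g = idx[i];
    if (g < 1 || g > ngroups) stop("group index out of range");
    out[g - 1] += x[i];
  }
  return out;
}
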