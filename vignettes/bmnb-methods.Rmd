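---
title: "Methods: the mixed negative-binomial model for genomic prediction of counts"
author: "bmnb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the mixed negative-binomial model for genomic prediction of counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Many phenotypes scored in plant-breeding trials are counts -- symptomatic
spikelets per spike, seeds per panicle, weeds per plot.  Counts are
non-negative, discrete, right-skewed and usually overdispersed, so Gaussian
genomic prediction models fit them poorly and can predict negative values.
`bmnb` implements genomic-enabled prediction for such data: a negative
binomial (NB) generalized mixed model whose random genetic effects carry a
marker-derived covariance (GBLUP), with an explicit
genotype-by-environment (GxE) term.

For replicate $t$ of line $j$ in block $k$ of environment $i$,

$$y_{ijkt} \mid g_j, gE_{ij} \sim \mathrm{NB}(\mu_{ijk}, r), \qquad
  \mu_{ijk} = \exp(\eta_{ijk}), \qquad
  \eta_{ijk} = E_i + R(E)_{ik} + g_j + gE_{ij},$$

with $E(y) = \mu$ and $\mathrm{Var}(y) = \mu + \mu^2/r$: the dispersion $r$
controls overdispersion and the Poisson model is the $r \to \infty$ limit.
The genetic values follow $g \sim N(0, G_1 \sigma_{b_1}^2)$ with
$G_1 = WW'/q$ the genomic relationship matrix over $q$ binary marker codes
(computed exactly in that form; an optional column-centred variant exists but
is off by default), and the GxE effects follow
$gE \sim N(0, G_2 \sigma_{b_2}^2)$ with $G_2 = I_I \otimes G_1$, i.e.
environments are conditionally independent and share the line covariance.
Because lines enter through $G_1$ rather than through per-marker
coefficients, the model remains estimable when markers far outnumber
records.

Writing $\pi = \mu/(r + \mu)$ turns the NB pmf into logistic form with
shifted predictor $\eta^* = \eta - \log r$ applied to the environment
coefficients ($\beta_i^* = \beta_i - \log r$; block coefficients are not
shifted).  Two data augmentations then make every conditional conjugate:

* a Polya-Gamma latent $\omega_{ijkt} \sim PG(y_{ijkt} + r, \eta^*_{ijk})$
  per record renders the conditionals of $\beta^*$, $g$, $gE$ Gaussian, with
  working response $\kappa = (y - r)/2$;
* a Chinese-restaurant-table latent $L_{ijkt} \sim CRT(y_{ijkt}, r)$ per
  record renders the conditional of $r$ gamma:
  $r \mid L, \pi \sim \Gamma\!\left(a_0 + \sum L,\;
  b_0 - \sum \log(1 - \pi)\right)$ (shape/rate).

The variance components have scaled-inverse-$\chi^2$ conditionals with
degrees of freedom $\nu + n_b$ and scale
$(b' G^{-1} b + \nu S)/(\nu + n_b)$.

## Order of the Gibbs updates

The gamma conditional for $r$ is derived from the collapsed NB likelihood in
$\pi$ -- that is, with $\omega$ integrated out.  This makes the sampler a
*partially collapsed* Gibbs sampler, and partially collapsed samplers are
only invariant under orderings in which a quantity that was marginalized out
is redrawn before anything conditions on it again.  `run_gibbs()` therefore
updates, per sweep:

1. $L \sim CRT(y, r)$ and then $r$ from its gamma conditional
   ($\omega$ collapsed);
2. $\omega \sim PG(y + r, \eta^*)$ given the *fresh* $r$;
3. $\beta^*$, then $g$, then $gE$ from their Gaussian conditionals using
   $\kappa = (y - r)/2$;
4. $\sigma_{b_1}^2$, $\sigma_{b_2}^2$ (and optionally
   $\sigma_\beta^2$).

Carrying an $\omega$ drawn under the previous $r$ into step 3 violates
invariance: in our experiments the variant that draws $\omega$ first holds
near the right posterior for a few hundred sweeps and then runs away along
the $\beta^* = \beta - \log r$ ridge ($r$ growing without bound while
$\beta^*$ compensates, with the variance components inflating in lockstep).
The ordering above eliminates the runaway and passes a
successive-conditional (Geweke-style) prior-invariance test on a small
model, a brute-force grid-posterior comparison, and per-conditional KS
tests; all three are in the test suite.

Because $gE$'s covariance is block-diagonal ($I_I \otimes G_1$) and
$Z_2' D_\omega Z_2$ is diagonal, the $IJ$-dimensional GxE draw factorizes
into $I$ independent $J$-dimensional solves, which is how `update_b2()`
computes it.  All Gaussian draws use Cholesky factorizations of the
conditional precision.

The GxE incidence matrix is built as the row-wise (face-splitting) product
of the $I$ environment indicator columns with the line incidence matrix,
giving $n_T \times IJ$ columns ordered environment-major -- the only
construction consistent with a GxE vector of length $IJ$ and
$G_2 = I_I \otimes G_1$ (the full fixed-effect design in the product would
give $J \cdot p$ columns).

## Latent-variable samplers

No closed-form sampler exists for $PG(b, c)$ with arbitrary real $b$, which
the model needs because $b = y + r$ with continuous $r$.  `rpg()` uses a
hybrid (compiled) scheme:

* integer part of $b$: a sum of exact Devroye-type $PG(1, c)$ draws
  (alternating-series rejection from a truncated-inverse-Gaussian /
  exponential mixture proposal), with the proposal constants hoisted across
  the repeated draws;
* fractional part in $(0, 1)$: the infinite gamma-convolution
  representation truncated after 12 terms, with the dropped tail replaced by
  a gamma variate matching the tail's exact mean and variance (both
  available in closed form from the PG moment formulas), so the first two
  moments are exact at every $b$;
* $b > 170$: a moment-matched normal.  This is the CLT regime; it is what
  makes the Poisson special case ($b = y + 1000$) cheap.  The closed-form
  variance is evaluated through an asymptotic expansion for $|c| > 30$ to
  avoid `sinh`/`cosh` overflow.

The tests verify the empirical mean and variance against
$E[\omega] = \tfrac{b}{2c}\tanh(c/2)$ and the matching variance formula over
$b \in \{0.5, \dots, 1000\}$, $c \in \{0, \dots, 10\}$, additivity in $b$ by
two-sample KS, and distributional agreement with a direct 2000-term
gamma-convolution oracle.

$CRT(y, r)$ is drawn by the defining sum of $y$ Bernoulli draws with success
probabilities $r/(l - 1 + r)$.  This is $O(y)$, which is fine for the counts
this model targets (at most a few hundred); a gamma-rate approximation for
very large counts exists in the literature but is deliberately not used.
Frequencies are tested against the exact Stirling-number pmf and the
digamma mean formula $r(\psi(r + y) - \psi(r))$.

## Priors and defaults

Real-data defaults (`prior_spec()`): $\beta^* \sim N(0, 10^4 I)$,
$\sigma_{b_h}^2 \sim \chi^{-2}(3, 0.001)$, $r \sim \Gamma(0.01, 0.01)$
(shape/rate) -- all weakly informative.  The fixed-effect variance scale
$\sigma_\beta^2$ is held at 1 unless the user supplies `nu_beta`/`S_beta`,
because the default prior is stated directly as $N(0, 10^4 I)$ without a
hyperprior.  Simulation-study priors (`simulation_priors()`):
$\chi^{-2}(0.50002, 4.0002)$ for both variance components and
$\Gamma(0.001, 0.001)$ for $r$, i.e. approximately flat.

With cell-means environment coding plus a full set of block indicators, the
fixed-effect design is rank-deficient; the proper prior regularizes this.
Under `flat_beta = TRUE` the improper flat prior cannot, so
`build_design(drop_last_block = TRUE)` removes one block column per
environment to restore full column rank.

Numerical safety: $\log(1 - \pi)$ is evaluated through the logistic
log-CDF (`plogis(..., lower.tail = FALSE, log.p = TRUE)`), so records with
large predictors cannot produce $\log 0$; the likelihood uses a piecewise
stable $\log(1 + e^x)$, making explicit clamping of $\eta^*$ unnecessary.
`covariance_set()` adds a $10^{-6}$ ridge to $G_1$ only when its Cholesky
factorization fails (real GRMs are often rank-deficient), with a message.
Chains are not thinned by default; `thin` exists as an option.
Initialization: $\beta^* = b_1 = b_2 = 0$, all variances 1, $r = 1$ (or the
fixed value).

Missing marker calls that survive `maf_filter()`'s missingness filter are
imputed to the marker's modal code -- a repository decision (the source
preprocessing states the MAF and missingness filters but no imputation
rule), kept minimal and reported via a message.

## The Poisson special case

`model = "pois"` fixes $r$ instead of sampling it, skipping the CRT step.
The fixed value follows the observed mean count (`auto_fix_r()`): 1000 below
50, 5000 from 50 to below 200, 10000 above; boundaries go to the larger
(more nearly Poisson) value.  The acceptance suite checks that on
Poisson-simulated data with mean below 50 the fixed-$r = 1000$ fit and the
dispersion-sampling fit give cell predictions agreeing within the posterior
predictive SD.

## What the simulator emulates

`simulate_panel()` generates from the model itself: Scenario 1 uses
$I = 3$, $J = 20$, $G_1 = I_{20}$,
$\sigma_{b_1}^2 = \sigma_{b_2}^2 = 0.5$, $\beta = (1.5, -1, 1)$, $r = 5$,
with $n \in \{5, 10, 20, 40\}$ replicates per environment-line cell and no
block effects; Scenario 2 changes $G_1$ to $0.7 I_{20} + 0.3 J_{20}$ to
imitate the between-line correlation real marker panels induce.  These
defaults are the study conditions; the latent truth is always returned for
recovery tests.

What passing recovery tests shows -- and what it does not: the simulator
draws from exactly the fitted model, so recovery demonstrates the sampler
explores the right posterior, not that the NB-with-GxE model describes any
particular real trial.  Real count data bring unbalancedness, zero
inflation, marker-derived (rank-deficient, unevenly weighted) relationship
matrices and block effects, which the scenarios do not exercise; the
multi-environment machinery is the same, but model adequacy must be judged
on the data at hand.

## Problem sizes used in the checks

Replicated recovery runs use 4,000 iterations with 2,000 burn-in and 10
replications at $n \in \{10, 20\}$ (5 at $n = 40$).  These sizes were chosen
as the point where the cross-replication SDs of the recovered parameters
stop shrinking noticeably relative to the benchmark values, so longer chains
mainly cost time; a production analysis of real data would still use long
chains (the 60,000/30,000 defaults of `bmnb_fit()`).  The Geweke-style
invariance check runs 4,000 successive-conditional sweeps on a
$2 \times 3 \times 2$-record model; the grid oracle integrates a
three-parameter posterior on a $61^3$ grid.

## Cross-validation choices

`cross_validate()` partitions records (not lines) uniformly at random into
$k$ mutually exclusive folds, sizes differing by at most one, re-drawing (up
to a bound) if some fold's training set loses an environment entirely;
per-environment stratification is available as a flag.  Which stratification
the benchmark study used is not stated, so pure record-level randomization
is this package's default.  Spearman correlations use average ranks for
ties; a constant observed or predicted vector yields `NA` with a warning
rather than a crash.  Predictions for held-out records average
$\exp(x'\beta^{*(s)} + \log r^{(s)} + g^{(s)} + gE^{(s)})$ over retained
draws; validation lines absent from a training fold are predicted through
their prior-conditional draws, which is precisely the GBLUP use case.
Scenario labels S1-S4 combine marker use (identity vs GRM line covariance)
with presence of the GxE term; rank-average tables summarize the two checks
across scenarios per environment.

## Known limitations

* The sampler targets counts up to a few hundred; the $O(y)$ CRT step and
  the $y + r$ PG shapes make very large counts slow (and the Poisson path
  with its normal-regime PG draws is then the right tool).
* Dispersion is shared across environments; heterogeneous $r_i$ would need
  a different augmentation bookkeeping.
* No zero-inflation component; panels dominated by structural zeros will
  show lack of fit.
* Marker-effect (Bayes-alphabet) parameterizations and pedigree
  relationship matrices are out of scope; the line covariance always enters
  as a matrix.
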