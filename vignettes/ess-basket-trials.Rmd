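---
title: "Quantifying information borrowing in basket trials by MSE-based effective sample size"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying information borrowing in basket trials by MSE-based effective sample size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(essbasket)
```

## The model

A basket trial enrols $n_k$ patients in each of $K$ indications and
observes responder counts $Y_k$. The package's central model is the
binomial Bayesian hierarchical model (BHM) on the log-odds scale:

$$Y_k \sim \mathrm{Bin}(n_k, p_k), \qquad
\theta_k = \mathrm{logit}(p_k) \sim N(\mu, \sigma^2), \qquad
\mu \sim N(\mu_0, s_0^2),$$

with the between-group variance $\sigma^2$ either fixed or given an
inverse-gamma hyperprior $\mathrm{IG}(a, b)$. The two bundled hyperprior
presets are `prior_A()` ($\sigma^2 \sim \mathrm{IG}(0.375, 1.5)$, moderate
borrowing — the configuration used in the RAGNAR trial's hierarchical
analysis) and `prior_B()` ($\sigma^2 \sim \mathrm{IG}(0.0005, 0.000005)$,
aggressive borrowing). Both use $\mu \sim N(-2.19, 2^2)$, centring the
common mean near an ORR of 10% with wide dispersion; all of these are
arguments of `prior_spec()` and can be replaced. The model assumes
exchangeable indications on the log-odds scale, a single binary endpoint,
and no interim adaptation. Setting $\sigma^2 = 0$ gives the pooled
analysis exactly (one logit parameter); very large fixed $\sigma^2$
approaches per-indication independent analysis.

## MSE-based effective sample size

The effective sample size translates a borrowing mechanism into patients.
The generic construction matches a posterior obtained with borrowing
against a posterior obtained from a *vague* prior updated with a
hypothetical sample of size $m + n_k$, minimising a distance in some
target measure. Here the target measure is the mean squared error of the
point estimator, because MSE = variance + bias$^2$ prices in exactly the
risk that matters when borrowing across heterogeneous indications.

For the independent comparator the estimator is the MLE
$\hat p = Y/(m + n_k)$, unbiased with MSE $p(1-p)/(m+n_k)$ — analytically
exact, including for fractional sample sizes. For the BHM the estimator is
the posterior mean $\hat p^B_k$ and its MSE must be obtained numerically:

* **Design stage** (`design_stage_ess()`): trials are simulated from
  assumed true rates $p_1, \dots, p_K$, the BHM is fitted to each, and the
  per-indication MSE is the Monte Carlo average of
  $(\hat p^B_k - p_k)^2$.
* **Analysis stage** (`analysis_stage_ess()`): the unknown $p_k$ is
  replaced by the observed rate $\hat p_k = y_k/n_k$, and the expectation
  runs over the binomial distribution of the own-indication outcome with
  the other indications fixed at their observed values. Because that
  support is finite, the package enumerates all $n_k + 1$ outcomes exactly
  (one fit each) rather than resampling — cheaper and free of a second
  layer of Monte Carlo error. All enumeration fits share one RNG seed so
  sampler noise does not masquerade as outcome variation.

The matching problem is solved by `ess_from_mse()`: a grid search over
integer $m \in [-n_k + 1, m_{\max}]$ for the minimiser of
$|p(1-p)/(m+n_k) - \mathrm{MSE}_B|$, refined to one decimal place by
linear interpolation of the signed distance between the two bracketing
integers. Since the signed distance is strictly monotone in $m$, the
interpolated root is within 0.2 of the exact solution
$p(1-p)/\mathrm{MSE}_B - n_k$ (a property the test suite sweeps). The
default cap $m_{\max} = 40\,n_k$ is deliberately generous — aggressive
priors produce prior ESS beyond twice the trial size — and an
out-of-range match returns status `"capped"` rather than an error.

Two degenerate regimes are handled explicitly. When the (observed) rate
is 0 or 1 the independent MSE is identically zero and no match exists;
the result carries status `"not_available"`. And the prior ESS is
*negative* whenever the Bayesian MSE exceeds the independent MSE at the
enrolled size — the bias contribution outweighs the variance reduction —
which is precisely the warning signal this definition is designed to
emit.

The bias-blind comparator `variance_ratio_ess()` defines posterior ESS as
$\bar p (1 - \bar p)/\mathrm{Var}(p_k \mid \text{data})$ with $\bar p$
the posterior mean. The exact published formula for this variant was not
available to us, so this plug-in binomial-information reconstruction is
used; for a $\mathrm{Beta}(a, b)$ posterior it equals $a + b + 1$
exactly, and on homogeneous data it tracks the MSE-based ESS. It never
goes negative, which is exactly why it is kept only as a comparator.

## Sampler

The BHM posterior is simulated with a purpose-built Gibbs scheme
(in C++ via Rcpp): conjugate draws for $\mu$ (normal) and $\sigma^2$
(inverse gamma given $\theta, \mu$), slice sampling for each $\theta_k$
(stepping-out and shrinkage; the full conditionals are log-concave), and
one joint Metropolis *translation* move per sweep that shifts $\mu$ and
all $\theta_k$ together. The translation move matters under aggressive
hyperpriors: when $\sigma^2$ collapses toward zero the $\theta_k$ are
pinned to $\mu$ and componentwise updates mix slowly in the common-level
direction; a joint shift restores mobility at negligible cost. Chains
initialise at the empirical logits (with a 0.5 continuity correction),
$\sigma^2$ at their spread, and $\sigma^2$ draws are floored at
$10^{-12}$ for numerical safety. $\sigma^2 = 0$ switches to an exact
pooled kernel (slice sampling the single logit). Everything runs on R's
RNG, so `set.seed()`/the `seed` field of `mcmc_settings()` makes every
fit bit-reproducible.

Default chain lengths are 5,000 iterations with 2,000 burn-in inside
simulation loops and 20,000/5,000 for single-dataset analysis — sized so
that per-fit Monte Carlo error in the posterior mean (a few $10^{-3}$) is
small against the binomial sampling variation that dominates the MSE.
The test suite validates the sampler against three independent routes:
one-dimensional quadrature in the pooled and independent limits, an
external JAGS fit of the identical model, and closed-form conjugate
results for the special cases.

## ESS-based designs and calibration

Three strategies use the ESS operationally:

* **Model selection** (`ess_based_model_selection()`): compute the
  analysis-stage prior ESS for every indication (under `prior_B()` by
  default, the setting in which negative values actually occur); if any
  is negative, analyse *all* indications independently with vague
  $\mathrm{Beta}(0.5, 0.5)$ priors. Indications with unavailable ESS
  (0%/100% observed) are excluded from the negativity check. The
  all-or-nothing rule is the default because it is the variant exercised
  in the simulation study; an `"exclude"` variant that drops only the
  offending indications from the hierarchy is provided for larger $K$.
* **Calibrated BHM** (`fit_cbhm()`): $\sigma^2 = \exp\{a + b \log T\}$
  with $T$ the Pearson chi-square statistic of the $K \times 2$
  responder table (uncorrected; the continuity-corrected variant was a
  genuine open choice and plain Pearson is the default because the
  statistic feeds a smooth map, not a test). $T$ is floored at $10^{-6}$
  and $\sigma^2$ clamped to $[10^{-4}, 10^4]$ to keep fits away from
  degenerate regimes; a non-computable $T$ (pooled rate 0 or 1) falls
  back to the weak-borrowing clamp.
* **Power prior** (`fit_power_prior()`): indication $k$'s posterior is
  $\mathrm{Beta}(s_{1,k} + \sum_i w_{k,i} y_i,\;
  s_{2,k} + \sum_i w_{k,i}(n_i - y_i))$ with self-weight 1 and
  $w_{k,i} = 1/(1 + \exp\{a + b \log S_{k,i}\})$, where
  $S_{k,i} = \max(n_k, n_i)^{1/4} S_{KS;k,i}$ and the two-sample KS
  statistic for binary data reduces exactly to the difference of observed
  proportions. $S = 0$ maps to weight 1 (the $b > 0$ limit). The initial
  Beta parameters default to 0.5/0.5, matching the vague prior used
  everywhere else; they were not pinned down externally. The fit also
  reports the nominal borrowed size $\sum_i w_{k,i} n_i - n_k$, though
  ESS reporting elsewhere always uses the MSE-based definition for
  comparability.

Two calibrations make designs comparable:

* `calibrate_phi()` finds the shared posterior-probability threshold
  $\phi$ at which the simulated per-indication rejection rate under the
  global null is closest to the target (5% by default). Tail
  probabilities are computed once per simulated trial, so the sweep over
  the $\phi$ grid (0.5–0.999, step 0.001; ties resolved toward the more
  conservative larger $\phi$) is essentially free. Note that for
  conjugate designs the achievable sizes are the discrete exact-test
  sizes, so "closest to 5%" may be 2.8% or 7.0%.
* `calibrate_tuning()` grid-searches $(a, b)$ against prior-ESS targets
  — by default the published ones: prior ESS around 30 (one trial's
  worth) for every arm of the global alternative, and 0 for the null arm
  of the most heterogeneous mixed scenario. How "around 30" is
  operationalised was an open choice; we minimise the equally-weighted
  sum of squared deviations on the grid ($a \in [-6, 6]$ step 0.5,
  $b \in [0, 2]$ step 0.1 by default), re-using one set of simulated
  datasets across all grid points so candidates face common Monte Carlo
  noise. On grids containing them, this recovers $(-2, 0.4)$ for the
  CBHM; for the power prior the objective is nearly flat in $b$ near the
  optimum, so the search lands on $a = 2$ with $b$ within one step of
  0.4.

## The simulation engine and the synthetic generator

`builtin_scenarios()` encodes the five-scenario study design: $K = 4$,
$n_k = 30$, null ORR 0.15, target ORR 0.3, with true rates ranging from
the global null (all 0.15) through mixed scenarios to the global
alternative (all 0.3). `generate_trial()`/the internal batch generator
draw $Y_k \sim \mathrm{Bin}(n_k, p_k)$ independently — this is the
complete data-generating process of the study design, so here the
generator is not an approximation to something richer. What it does *not*
emulate about real trials: accrual over time, per-indication
heterogeneity beyond the binomial (e.g. site effects), misclassified
responses, and dropout. Conclusions from passing tests therefore concern
the statistical machinery under the stated design, not robustness to
those real-data complications.

`run_operating_characteristics()` crosses scenarios with designs and
reports per-indication rejection percentage, MSE of the posterior-mean
estimate, and the design-stage prior ESS derived from the pooled
replication set (the ESS is a functional of the MSE — an expectation —
not of any single replication). Reporting follows the field's precision
conventions: ESS to one decimal, MSE in units of $10^{-3}$, rejection in
percent. `summarize_by_truth()` averages exchangeable arms (same true
ORR within a scenario) into "A"/"N" groups.

## Problem sizes and Monte Carlo error

The published study used 10,000 replications per scenario. The package
defaults to 1,000 in the engine, and the bundled acceptance script uses
2,000 (4,000 for $\phi$ calibration) — sizes chosen so a full
reproduction runs in about a minute on one core while keeping Monte
Carlo noise quantified and small: at 2,000 replications the relative
standard error of an MSE estimate is about 3%, which propagates (via the
delta method, reported as the `ess_se` attribute) to roughly ±3 patients
on a prior ESS of 74; rejection rates carry the usual binomial standard
error, about 1.1 points at 50% and 0.4 points at 96%. All replication
counts are arguments.

## Known limitations

* The analysis-stage ESS costs $n_k + 1$ MCMC fits per indication;
  for model-selection simulations this is the dominant cost, mitigated by
  shorter chains for the decision step (`ess_settings`).
* The exact one-sided binomial benchmark at $n = 30$, $p_0 = 0.15$,
  $\alpha = 5\%$ has critical count 9, size 2.78% and power 56.85% at
  $p = 0.3$; published summaries sometimes round this benchmark to 58%,
  which no standard exact-test convention reproduces (mid-$p$ gives
  71.9%). The package reports the exact value.
* The variance-ratio ESS is a reconstruction (see above), and the
  treatment-difference parameterisation
  $\theta_k = \mathrm{logit}(p_k) - \mathrm{logit}(p_{k0})$, alternative
  distance measures (relative entropy, log-density curvature),
  randomized/adaptive basket designs and multiple endpoints are out of
  scope.
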