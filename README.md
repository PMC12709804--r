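# essbasket

Effective sample size (ESS) for information borrowing in Bayesian basket
trials.

## The problem

A basket trial tests one therapy across several tumor types (indications)
that share a molecular target, each indication contributing a small
single-arm cohort with a binary response endpoint. Bayesian hierarchical
models (BHMs) borrow information across indications to gain power, but the
*degree* of borrowing is controlled by an opaque hyperparameter — the
between-group variance σ² of the indication-level log-odds effects — whose
value is hard to interpret and to communicate to non-statisticians.
Borrowing also carries a real risk: when indications are heterogeneous, the
shrinkage that reduces variance also biases the per-indication estimates
and inflates the type I error.

`essbasket` quantifies borrowing in the most interpretable unit available —
patients. It is aimed at trial statisticians designing or re-analysing
phase II basket trials who need to report, calibrate, or cap how much
extra information each indication effectively receives.

## The method

The model is the standard binomial BHM

    Y_k ~ Bin(n_k, p_k),  θ_k = logit(p_k) ~ N(μ, σ²),  k = 1, …, K,

with μ ~ N(μ₀, s₀²) and σ² either fixed or given an inverse-gamma
hyperprior. The *posterior ESS* for indication k is the sample size m + nₖ
at which an *independent* binomial analysis would match the mean squared
error of the Bayesian estimator p̂ᵏᴮ (the posterior mean):

    find m minimising | p(1−p)/(m+nₖ) − MSE(p̂ᵏᴮ) |,

and the *prior ESS* is m, the information borrowed from the other
indications. Because the target measure is MSE = variance + bias², the
prior ESS is penalised — and can go negative — when borrowing-induced bias
dominates, exactly the situation a trialist needs to be warned about.
At the design stage MSE(p̂ᵏᴮ) is computed by Monte Carlo over simulated
trials at the assumed true rates; at the analysis stage the observed rate
y_k/n_k stands in for the truth and the expectation is enumerated exactly
over the n_k + 1 possible own-indication outcomes. A variance-ratio ESS
(posterior ESS = p̄(1−p̄)/Var(p_k | data)), which ignores bias, is included
as a comparator.

On top of the ESS the package implements three borrowing strategies:

- **ESS-based model selection** — fall back to independent Beta(0.5, 0.5)
  analyses when any indication shows a negative analysis-stage prior ESS;
- **calibrated BHM (CBHM)** — σ² = exp{a + b·log T} with T the Pearson
  chi-square heterogeneity statistic, (a, b) calibrated against prior-ESS
  targets instead of target variances;
- **ESS-based power prior** — conjugate pairwise borrowing with logistic
  weights w = 1/(1 + exp{a + b·log S}) driven by scaled Kolmogorov–Smirnov
  similarities S.

A simulation engine produces operating characteristics (per-indication
rejection rate, MSE, mean prior ESS) across scenarios and designs, with
posterior-probability rejection thresholds φ calibrated to a target type I
error under the global null.

## Worked example

```r
library(essbasket)
d <- read_basket_csv(system.file("extdata", "synthetic_basket.csv",
                                 package = "essbasket"))
rep <- analyze_basket(d, prior_A(),
                      settings = mcmc_settings(20000, 5000, seed = 1),
                      ess_settings = mcmc_settings(5000, 2000, seed = 1))
print(rep)
```

```
Basket analysis [Prior A], pooled ORR 28.4%
 indication  n y   orr ci_lower ci_upper post_mean cri_lower cri_upper
  cholangio 20 9 0.450    0.231    0.685     0.418     0.222     0.628
     breast 16 5 0.312    0.110    0.587     0.297     0.122     0.517
 pancreatic 15 3 0.200    0.043    0.481     0.203     0.057     0.409
 glioma_low  7 2 0.286    0.037    0.710     0.269     0.059     0.587
   prostate  9 0 0.000    0.000    0.336     0.084     0.001     0.287
 prior_ess    ess_status
     1.271            ok
     4.592            ok
     6.084            ok
     5.089            ok
        NA not_available
sigma2 posterior (2.5/50/97.5%): 0.455 / 1.87 / 14.6
```

Reading the report: each row contrasts the frequentist estimate (observed
ORR with an exact Clopper–Pearson 95% CI) with the hierarchical posterior
mean and credible interval. The BHM shrinks every arm toward the pooled
28.4% and narrows the intervals. The prior ESS column says what that
shrinkage is worth: the pancreatic cohort (ORR 20%, close to the pool)
effectively gains about 6 patients, while the cholangiocarcinoma cohort
(ORR 45%, far from the pool) gains barely 1 — its variance reduction is
almost cancelled by bias. The zero-responder prostate arm has no ESS:
with an observed rate of 0% the independent-analysis MSE is identically
zero and the matching problem is undefined.

Design-stage use, on the built-in five-scenario study (K = 4, n = 30):

```r
sc <- builtin_scenarios()
design_stage_ess(sc$S1, prior_B(), reps = 2000, seed = 1)  # ~ +73 per arm
design_stage_ess(sc$S5, prior_B(), reps = 2000, seed = 1)  # arm 4 ~ -15
```

Under the aggressive-borrowing hyperprior (Prior B), every arm of the
global null effectively gains more than twice its own sample size, but the
single null arm of the mixed Scenario 5 *loses* the equivalent of ~15
patients — the quantitative warning that this prior over-borrows.

A thin command-line front end is installed at
`system.file("cli", "basket-ess", package = "essbasket")` with subcommands
`analyze`, `simulate`, `ess-design`, `ess-analysis`, `calibrate-phi`,
`calibrate-tuning` and `fixtures`.

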