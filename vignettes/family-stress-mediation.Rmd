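---
title: "Decomposing income effects on child mental health: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing income effects on child mental health: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqmediate)
```

## The scientific problem

Children in low-income households have worse mental-health outcomes, and the
family stress model proposes a mechanism: economic hardship erodes parental
(especially maternal) wellbeing, which degrades parent--child relationship
quality, which in turn harms the child's emotional and behavioural
development. `seqmediate` implements the counterfactual machinery needed to
quantify this chain in a birth-cohort setting: how much of the total effect
of low income on later child mental-health difficulty travels through
maternal wellbeing, through relationship quality, through both sequentially,
and how much bypasses them.

All variables are dichotomised, because with binary exposure and mediators
there is a single counterfactual state per index and the natural-effects
decomposition has a clean odds-ratio form:

* `X` -- household in the bottom two quintiles of OECD-equivalised income;
* `M1` -- mother in the top quintile of a six-item DASS score
  (reduced maternal wellbeing, measured after exposure);
* `M2` -- dyad in the lowest closeness or highest conflict quintile of the
  CPRS-SF (poor relationship quality, measured after `M1`);
* `Y` -- SDQ total difficulties score of 17+ ("abnormal" band);
* `C` -- six binary baseline confounders (low maternal education, maternal
  age under 20 at first birth, maternal unemployment, more than four
  children, one-parent family, ethnic minority).

## The estimator

We use an imputation-based natural-effects approach extended to two causally
ordered mediators. Three counterfactual exposure indices are introduced:
`x0` feeds the direct path, `x1` the path through `M1`, and `x2` the path
through `M2`. Two weighted logistic working models are fitted: an outcome
imputation model `P(Y=1 | x, m1, m2, c)` and a first-mediator model
`P(M1=1 | x, c)`. Each child is then expanded to the four settings
`(x0, x1) in {0,1}^2`, with `x2` pinned at the child's observed exposure,
and given the imputed counterfactual expectation

```
E(x0, x1) = sum_{m1} P(M1 = m1 | x1, c) * P(Y = 1 | x0, m1, m2_obs, c).
```

A fractional-response logistic "natural model"

```
logit E{ Y(x0, M1(x1), M2(x2, .)) } = th0 + th1 x0 + th2 x1 + th3 x2 + c'g
```

is fitted to the expanded records with the survey weights. The effects are
read off the coefficients: `OR_NDE = exp(th1)`, `OR_NIE(M1) = exp(th2)`,
`OR_NIE(M2) = exp(th3)`, with the joint indirect effect `exp(th2 + th3)`
and total effect `exp(th1 + th2 + th3)`. Two consequences are worth
stating:

* the decomposition `OR_TE = OR_NDE x OR_NIE(joint)` holds *exactly*, by
  construction, on every fit -- it is asserted in the tests to machine
  precision;
* the "in isolation" indirect effects are read off `th2` and `th3` of the
  single sequential model. This additive-index structure is what makes the
  joint NIE the product of the separate NIEs, the same structure visible in
  published applications of the approach.

The proportion mediated is computed on the odds-ratio scale as
`PM = OR_NDE (OR_NIE - 1) / (OR_NDE * OR_NIE - 1)`; `PM(x, 1) = 0` and
`PM(1, x) = 1` identically.

### Design choices that were genuinely open

**Expansion scheme.** The method we reconstruct is described in the
literature only at the level of "natural effect models for multiple
mediators". We chose the variant that expands over `(x0, x1)` and pins
`x2` to the observed exposure, because the second mediator's counterfactual
distribution (which depends on `M1` under `x2`) is then never modelled
explicitly -- the observed `m2` plays that role. The cost is that `th3` is
identified from between-child variation; confounders in the natural model
carry that adjustment.

**Interactions.** Exposure--mediator (`X:M1`, `X:M2`) and
mediator--mediator (`M1:M2`) terms in the outcome imputation model are
available but off by default: without them the natural-model odds ratios
transport cleanly and the decomposition has the product form above.

**Weights.** Longitudinal survey weights enter every working model and the
natural model as estimating-equation weights; the bootstrap resamples
children and carries their weights. Weights are *not* used inside the
imputation models (the convention when weights re-enter at analysis stage).

**Inference.** Percentile bootstrap over child-level resampling (default
`B = 1000`), matching a non-parametric bootstrap with no stated variance
formula. With multiple imputation the point estimates are Rubin-pooled
(arithmetic mean of `theta` on the log-odds scale) over `m = 20`
imputations, and each bootstrap replicate resamples rows *then* performs
one stochastic imputation ("boot-then-impute"), so the intervals carry both
sampling and imputation uncertainty. How the original analysis combined its
bootstrap with its 20 imputations is not stated anywhere we could find;
this scheme is one defensible choice, recorded here deliberately.

**Separation.** Any working-model fit that separates (non-convergence or
runaway coefficients) falls back to a weakly ridge-penalised IRLS fit with
a warning; inside bootstrap replicates the fallback is silent and failures
are counted instead (more than 5% failed replicates is an error).

## Upstream derivations

* **Equivalisation**: income divided by `1 + 0.5 (adults - 1 + others 14+)
  + 0.3 x children under 14` (OECD-modified scale).
* **Quintile flags**: the cut is the smallest observed value whose weighted
  ECDF reaches the target mass; ties at the cut are flagged ("at or below"
  inclusion, conservative toward exposure). The exposure rule is
  bottom-two-quintiles; a below-60%-of-median alternative is provided
  because the two definitions are *not* equivalent and the quintile rule is
  the one consistent with the published Low/Medium-High split. Quintiles
  are computed unweighted by default (whether the original cuts were
  survey-weighted is unstated); a weighted mode is provided.
* **SDQ banding**: normal < 14, borderline 14--16, abnormal >= 17; the
  outcome flag is the abnormal band.
* **DASS**: six items scored 0--3 (the standard response format; the source
  lists the items but not the ranges), summed; top quintile flagged; any
  missing item makes the flag missing.
* **CPRS-SF**: lowest closeness quintile *or* highest conflict quintile;
  with one subscale missing the flag is 1 if the observed subscale already
  qualifies, else missing.

### Reference cut-offs versus in-sample quintiles

A quintile flag computed *within* a sample always marks at least 40% of it.
An analysis subsample of a larger cohort, however, can show a different
flagged share -- the published analysis sample is 38.9% "exposed" precisely
because its quintile cuts were formed on the full cohort. We reproduce
this: the simulator draws flags from the structural model (prevalence
38.9%) and back-generates raw scores against fixed population cut-offs,
which it records in `attr(cohort, "cutpoints")`. `derive_analysis_set()`
uses such reference cut-offs when supplied (giving exact flag round-trips)
and falls back to in-sample quintiles otherwise (the only option with real
data and no documented cuts).

## Missing data

`littles_mcar_test()` implements the classical chi-square MCAR test with a
from-scratch EM algorithm for the multivariate-normal mean and covariance
under arbitrary missingness. Factors are coerced to numeric level codes --
the convention of the widespread SPSS implementation -- so for binary and
ordinal data the test is approximate. Complete data give `df = 0` and a
"not applicable" report; singular observed-block covariances are
ridge-regularised (`eps = 1e-6`) with a warning.

`chained_impute()` is a from-scratch MICE: logistic draws for binary
variables, nested binary logits for factors (no multinomial backend is
assumed), and predictive mean matching (5 donors, type-1 matching) for
continuous variables; proper parameter draws from each fit's approximate
normal posterior; chains initialised from observed marginals; the last of
`n_iterations` cycles kept; defaults `m = 20`, `n_iterations = 50`.
Observed cells are never altered. `compare_imputed()` mirrors the usual
observed-vs-imputed diagnostic (standardised differences and two-sample
tests).

One tension is reproduced deliberately: the original workflow reports that
its data were *not* missing completely at random yet proceeds with MICE,
which assumes MAR. The package reproduces the procedure and surfaces the
caveat here rather than "fixing" it.

## The synthetic cohort and its calibration

The simulator draws six independent binary confounders, then `X`, `M1`,
`M2`, `Y` from logistic structural equations in causal order -- the family
stress chain with a direct path retained. Default coefficients are
calibrated so the population marginals equal the published analysis-sample
values: exposure 38.9%; `M1` 30.6%/18.4%, `M2` 40.6%/31.5%, `Y` 8.3%/2.7%
by exposure stratum. Because the confounders are binary and independent,
the calibration is solved *exactly* by enumerating the 64 confounder
patterns (the intercept and exposure-coefficient pairs are the only free
parameters; confounder slopes on `X` are anchored to published unadjusted
odds ratios and slopes on `M1`/`M2`/`Y` are fixed modest values, OR
1.2--1.8, chosen once as plausible adjusted associations).

Raw scores are back-generated from the flag side of each cut-off
(e.g. SDQ uniform on 17--40 when `Y = 1`; the non-abnormal band is split
normal/borderline 90.4:4.9 to echo the published banding); equivalised
income is log-normal (`meanlog = log 22000`, `sdlog = 0.6`, a plausible UK
equivalised-income shape) truncated to the relevant side of its population
40th percentile and de-equivalised through the generated household
composition. Missingness is injected last: MCAR, MAR (score missingness
driven by one-parent and unemployment flags), or MNAR (driven by the score
itself), with per-variable default rates matching the published missing
counts (income 8.0%, SDQ 7.9%, confounders 1--2%).

What the generator does *not* emulate: clustered survey design, realistic
attrition weights (weights default to 1, with a mean-one log-normal
option), item-level DASS/CPRS response correlation structure, or
stratum-specific raw-score distributions (only banded prevalences are
published, so only prevalences are calibrated). A green recovery test
therefore establishes that the estimator recovers the effects implied by
this structural world -- not that the published point estimates are
correct.

## The ground-truth oracle

`oracle_effects()` computes population natural effects by Monte Carlo over
the confounder draw, Rao-Blackwellised within draw: given `C`, the
counterfactual outcome probability of each index setting is evaluated in
closed form, with the copy of `M1` entering the outcome (at `x1`)
integrated independently of the copy driving `M2` (at `x2`) -- exactly the
estimand the expansion-imputation estimator targets. Effects are odds
ratios between successive counterfactual probabilities at `(0,0,0) ->
(1,0,0) -> (1,1,0) -> (1,1,1)`, so `TE = NDE x NIE(joint)` holds exactly.
Degenerate probabilities (0 or 1) set an `unbounded` flag instead of
crashing.

These oracle odds ratios are *marginal* (confounder-averaged); the natural
model's `exp(theta)` are conditional on `C`. Odds ratios are not
collapsible, so the two differ in principle. In the calibrated world the
outcome is rare and the gap -- computed exactly from the estimator's
population limit on the enumerated confounder distribution -- is below
0.005 on the log-OR scale, well inside the recovery tolerance used in the
tests; with common outcomes or strong confounder effects it would not be.

## Numerical choices and degenerate inputs

* Quantile cuts: smallest observed value reaching the target weighted ECDF
  mass; an all-constant vector has no quintile -- all-unflagged plus a
  warning.
* Zero cells in a 2x2 table: +0.5 continuity correction of all cells, with
  a warning; Woolf (log-normal) intervals throughout, which is the interval
  that reproduces the published descriptive CIs.
* Display rounding is half-up (2 dp for odds ratios, 1 dp for
  percentages); all stored values are unrounded.
* PM with `OR_NDE x OR_NIE` within machine epsilon of 1: `NA` with an
  `undefined` attribute.
* Ridge fallbacks: logistic separation `lambda = 1e-2` (intercept
  unpenalised); singular EM blocks `eps = 1e-6`.
* Seeds: every public stochastic function takes one master seed and derives
  sub-streams deterministically (`derive_seeds()`), so same seed means
  bit-identical output end to end, including file outputs of
  `run_pipeline()`.

## Known limitations

* Exposure-induced mediator--outcome confounding is not adjustable in this
  estimator -- an acknowledged limitation of the method itself, not an
  implementation gap.
* Continuous exposures or mediators are out of scope (everything is
  dichotomised by design).
* The MCAR test's normal approximation for categorical data, the MAR
  assumption inside MICE, and the unweighted-quintile default are
  approximations documented above.
* Bootstrap coverage: percentile intervals with a rare outcome are known
  to undercover somewhat at small n; coverage checks in the test suite are
  run at the study-scale n (3639), where the working models are
  well-behaved.
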