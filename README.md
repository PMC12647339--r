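# seqmediate

Counterfactual mediation analysis for the **family stress model**: how much
of the effect of growing up in a low-income household on a child's later
mental-health difficulties travels through reduced maternal wellbeing,
through poor parent–child relationship quality, through both acting
sequentially — and how much bypasses them.

The package is written for epidemiologists working with birth-cohort data
(exposure, two causally ordered binary mediators measured at successive
sweeps, binary outcome, baseline confounders, longitudinal survey weights).
Because such cohort data are typically access-restricted, a calibrated
synthetic cohort generator with a Monte-Carlo counterfactual oracle is a
first-class component, so every stage of the pipeline is testable against a
recoverable ground truth.

## The decomposition

For binary exposure `X` (low equivalised household income), ordered binary
mediators `M1` (reduced maternal wellbeing) and `M2` (poor child–parent
relationship quality), binary outcome `Y` (SDQ total difficulties ≥ 17) and
baseline confounders `C`, the natural-effects model is a fractional-response
logistic regression on counterfactually expanded data with three exposure
indices:

    logit E{ Y(x0, M1(x1), M2(x2, ·)) } = θ0 + θ1·x0 + θ2·x1 + θ3·x2 + C'γ

giving `OR_NDE = exp(θ1)`, `OR_NIE(M1) = exp(θ2)`, `OR_NIE(M2) = exp(θ3)`,
`OR_NIE(joint) = exp(θ2+θ3)` and `OR_TE = exp(θ1+θ2+θ3)`, so
`OR_TE = OR_NDE × OR_NIE(joint)` holds exactly on every fit. The proportion
mediated is `PM = OR_NDE(OR_NIE − 1) / (OR_NDE·OR_NIE − 1)`.

Counterfactual outcome expectations are imputed from two weighted logistic
working models (an outcome model and a first-mediator model), each child
being expanded to the four `(x0, x1)` settings with `x2` pinned at the
observed exposure. Inference is by child-level non-parametric percentile
bootstrap (default `B = 1000`); missing flags are handled by built-in
chained-equation multiple imputation (default `m = 20`, 50 iterations) with
Rubin-pooled points and boot-then-impute intervals. See the methods
vignette (`vignettes/family-stress-mediation.Rmd`) for assumptions, design
decisions and limitations.

Also included: OECD-modified income equivalisation, weighted quintile
flags, SDQ banding, DASS/CPRS-SF scoring, Little's MCAR test (from-scratch
multivariate-normal EM), imputation diagnostics, and descriptive
exposure-stratified odds-ratio tables with Woolf intervals.

## Worked example

```r
library(seqmediate)

params <- structural_params(n_children = 20000, seed = 1)   # calibrated defaults
cohort <- generate_cohort(params, inject_missing = FALSE)
aset   <- derive_analysis_set(cohort, cutpoints = attr(cohort, "cutpoints"))

fit <- natural_effects(aset)
print(fit)
#> Natural effects decomposition (odds-ratio scale)
#>   Total Effect              2.36
#>   Natural Direct Effect     2.22
#>   NIE via M1                1.03  PM 5.82%
#>   NIE via M2                1.03  PM 4.86%
#>   Joint NIE via M1 and M2   1.06  PM 10.29%

oracle_effects(params, n_mc = 1e6, seed = 1)   # ground truth for this world
#> Monte-Carlo ground-truth natural effects (marginal odds ratios)
#>   TE          2.244  (MC se of log OR 1.25e-05)
#>   NDE         2.109  (MC se of log OR 1.39e-05)
#>   NIE(M1)     1.039  (MC se of log OR 4.77e-06)
#>   NIE(M2)     1.024  (MC se of log OR 1.42e-06)
#>   NIE(joint)  1.064  (MC se of log OR 6.09e-06)
```

Reading this: in the simulated cohort of 20,000 children, exposure to low
income multiplies the odds of a high-difficulties SDQ score by ≈2.4 in
total; holding both mediators at their unexposed values still multiplies
them by ≈2.2 (the direct path), while the two mediated paths jointly
account for ≈10% of the effect on the odds-ratio scale. The single-cohort
estimates sit within sampling error of the Monte-Carlo truth (TE 2.24,
joint NIE 1.06).

Descriptive tables use the same analysis set:

```r
exposure_stratified_table(aset, c("Y", "M1", "M2"))
#>   variable n_exposed pct_exposed n_unexposed pct_unexposed  or_ ci_low ci_high
#> 1        Y       670        8.59         333          2.73 3.35   2.93    3.83
#> 2       M1      2388       30.62        2357         19.32 1.84   1.73    1.97
#> 3       M2      3149       40.38        3817         31.28 1.49   1.40    1.58
```

With missing data the full procedure is one call (Little's MCAR test,
chained imputation, decomposition, bootstrap, report files):

```r
cfg <- run_config(params = structural_params(n_children = 3639, seed = 1),
                  m = 20, n_iterations = 50, B = 1000, out_dir = "run1")
res <- run_pipeline(cfg)
```

which writes `sample_characteristics.csv`, `exposure_stratified.csv`,
`effects.csv`, `imputation_diagnostics.csv`, a machine-readable `fit.json`
(θ, ORs, CIs, PMs, all seeds) and a log. A command-line front end with
`simulate` / `validate` / `mcar-test` / `derive` / `run-all` subcommands is
in `inst/cli/seqmediate.R`.

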