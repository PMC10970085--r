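---
title: "Composite stress indices from complex survey data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite stress indices from complex survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressindex)
```

## The problem

Allostatic load (AL) operationalizes cumulative physiological stress as a
count of biomarkers in high-risk ranges. The Chronic Stress Indicator
(CSI) asks whether replacing half of those biomarkers with
socio-behavioral risk factors — education, poverty, alcohol, tobacco,
physical inactivity — yields a composite that better captures
stress-related outcomes. Comparing the two indices on a national
examination survey requires design-based statistics throughout: the data
come from a stratified multi-stage sample with strongly unequal weights,
so naive variance formulas and tests are wrong. This package implements
both the index construction and the design-based comparison battery, plus
a synthetic cohort generator so that every stage is testable against
known ground truth.

## Index construction

Both indices are sums of ten binary components, classified high-risk at a
fixed threshold: 5 of 10 for the CSI, 3 of 10 for AL. The CSI's
socio-behavioral components come from deterministic recodes of the survey
vocabulary:

* **Poverty**: income bracket with upper bound at or below $20,000 (the
  averaged 2001–2004 federal poverty-guideline endpoints, $17,650 and
  $18,850, give $18,250; the classification bound is the enclosing coarse
  bracket boundary). The coarse "Less/More than $20,000" alternatives map
  to 1/0 directly; the eleven fine brackets resolve by their upper bound.
* **Education**: below a high-school diploma (the two lowest of the five
  levels) is high-risk.
* **Alcohol**: twelve or more drinks in a year, boundary inclusive.
* **Smoking**: at least one cigarette in the past month.
* **Physical inactivity**: non-participation is high-risk. "Unable to Do"
  is also scored high-risk: only participation is defined as protective,
  so treating inability as non-participation is the conservative reading.
  This is a genuine judgment call; the recode is a small pure function if
  a user wants the alternative.

Biomarker components use **quartile cutoffs from the analyzed sample**
rather than clinical guideline values: a marker scores 1 at or beyond the
75th percentile ("within the top 25 percent" read inclusively), or at or
below the 25th for protective markers. Three design choices deserve
explanation:

* *Weighting*: cutoffs default to unweighted sample quantiles — "the
  study distribution" most plainly means the sample at hand — with a
  survey-weighted option recorded in the cutoff provenance. With equal
  weights the two agree exactly, which the tests assert.
* *Timing*: cutoffs are derived before complete-case filtering, on all
  records observed for each marker, which maximizes their stability; the
  choice is configurable and the per-marker `n_used` is recorded.
* *Directions*: HDL and albumin are protective (bottom-quartile risk);
  SBP, DBP, TC, HbA1c, BMI, TG and CRP are top-quartile risks. Creatinine
  clearance is genuinely ambiguous — both renal hyperfiltration and
  decline are reported stress correlates — and defaults to top-quartile
  risk; all directions are configurable and logged.

The weighted quantile uses the left-inclusive convention: the smallest
observed value whose weighted CDF reaches `q`. This matches the
integer-weight expansion oracle (repeat each record `w_i` times, take the
empirical quantile), which is how the tests verify it.

Each index drops records missing any of its own ten components
(complete-case per index), so the two analysis samples differ — as they
do in real extracts, where the AL and CSI samples have different sizes.

## Design-based estimation

All estimators take a `svy_design` (stratum, PSU, weight) and use Taylor
linearization with the stratified between-PSU variance estimator — the
standard recommendation for public-release designs with pseudo-strata
and pseudo-PSUs. Design degrees of freedom are PSUs − strata. Strata
with a single PSU are an error by default; an explicit
`lonely_psu = "certainty"` option lets them contribute zero variance,
with a loud warning, for designs where singleton strata are true
certainty units.

* **Means and proportions** are ratio estimators; linearized residuals
  `w_i (x_i − x̄)/W` are summed to PSU totals and their between-PSU
  variance accumulated within strata. With equal weights and each record
  its own PSU this reduces to the classical SRS formula exactly.
* **Rao–Scott chi-square**: the Pearson statistic is computed on weighted
  cell proportions scaled to the unweighted n, and its distribution
  corrected by the estimated generalized design-effect matrix Δ (the
  linearized covariance of the cell proportions against the multinomial
  covariance, projected onto the interaction-contrast space). The
  second-order (Satterthwaite) form is reported as
  `F = X² / tr(Δ)` on `(d₀, d₀·df_design)` df, `d₀ = tr(Δ)²/tr(Δ²)`.
  An F rather than chi-square reference is used because the design
  covariance is itself estimated on few design df; the choice is visible
  in the returned `method`.
* **Rank-sum test**: each value is replaced by its estimated population
  rank — the weighted mid-CDF score `(F_w(x⁻) + F_w(x))/2`, scaled to
  [0, 1] by the total weight so the statistic is weight-scale-free — and
  the difference in the two groups' weighted mean rank scores is tested
  with a Wald t statistic on the design df, with the covariance of the
  two domain means estimated jointly. Under equal weights and an iid
  design this tracks the classical normal-approximation rank-sum p-value
  closely (asserted at median |Δp| < 0.02 in the tests).
* **Survey logistic regression**: IRLS on the weighted
  pseudo-log-likelihood to a score norm below 1e−8 (at most 50
  iterations, with the convergence trace kept in the fit record), with
  coefficients diverging past |β| > 30 reported as separation naming the
  term. Variance is the linearized sandwich `A⁻¹ B A⁻¹`; CIs are
  `exp(β ± t_{df,0.975}·SE)`, and p-values use the same t reference, so
  p < 0.05 if and only if the 95% CI excludes 1. A design-weighted
  pseudo-likelihood has no canonical AIC; the reported value normalizes
  weights to sum to n before evaluating the likelihood, making it
  comparable across models fitted here but **not** across software.

p-values below 0.05 are treated as significant throughout (configurable
`alpha` in the pipeline); every reported p is traceable in the run
manifest to its test, variables, n and design df.

## Association diagnostics

Cramér's V (`sqrt(χ²/(n·min(r−1, c−1)))`, classical Pearson χ² on the
unweighted table, no bias correction) and the VIF are computed
unweighted: neither has a standard design-based version in routine use,
and the weighted Pearson correlation is offered as an option while
defaulting to unweighted. Categorical predictors enter the VIF as
indicator blocks via the generalized (determinant-ratio) VIF with the
df-adjusted `GVIF^(1/2df)` reported alongside; exact collinearity is
reported as an infinite VIF on the offending variables rather than an
error, since flagging it is the diagnostic's whole point. Published VIF
values from any particular analysis depend on the exact design matrix
(coding, reference levels, variable set), so the module exposes the
predictor list rather than hard-coding one.

## Exploratory factor analysis

The EFA module fits maximum-likelihood factor solutions on the Pearson
correlation matrix of each index's ten scored 0/1 components — the most
direct reading of "the variables associated with" each index — with raw
continuous markers accepted as an alternative input, and tetrachoric
correlations deliberately not defaulted (Pearson-on-binary attenuates
correlations somewhat; the factor-count test is on the correlation
structure actually used to build the additive index). Estimation is
`stats::factanal` (ML with multiple random restarts under a fixed seed);
the package adds the k = 0 case — Bartlett's sphericity test, the
natural "no factors needed" null — SS loadings, cumulative variance
`cumsum(ss)/p`, Heywood-case flagging, and the factor-number scan table.
The reported chi-square uses the Bartlett correction
`(n − 1 − (2p+5)/6 − 2k/3)·discrepancy` with
`df = ((p−k)² − (p+k))/2`. Solutions with df = 0 (e.g. p = 3, k = 1) are
admitted — they are exactly identified, and the closed-form one-factor
solution is a test oracle — with the test reported only when df > 0. No
rotation is applied for reporting: SS loadings and cumulative variance
are rotation-invariant, and those are the quantities the scan table
reports. Uniquenesses are returned as 1 − communality exactly, so the
communality identity holds by construction.

## The synthetic cohort generator

The generator emulates the design features that matter to the
estimators, with defaults chosen once as the study conditions:

* **Design**: 15 strata × 2 PSUs × 140 records (n = 4200, the scale of a
  two-cycle extract of 20–49-year-olds), lognormal weights (sdlog 0.5)
  rescaled to a population total of 25 million. The population total is a
  free parameter because multi-cycle weight construction is
  survey-specific.
* **Demographics and behaviors**: age uniform on 20–49, the five
  race/ethnicity classes at roughly national proportions, education and
  the five-level vocabulary as printed, income bracketed from a
  continuous lognormal (median $40,000) with a 5% coarse-report fraction
  exercising the "Less/More than $20,000" recode path, smoking ~30%,
  drinking with a zero-inflated lognormal count, inactivity ~66% with a
  1% "Unable to Do" sliver, occupations drawn from the shipped
  low/high-activity vocabulary.
* **Biomarkers**: multivariate normal at clinically plausible means
  (matching published overall survey means where available) with a
  plausible correlation structure whose strongest pairwise relation is
  HDL–TG at −0.4, clipped to physiologic floors (e.g. BMI ≥ 12) so
  quartiles stay well-defined. Clipping is a monotone per-marker
  transform and cannot manufacture cross-marker correlation.
* **Latent risk**: a logistic model
  `logit p = α + β_age(age−35) + β_male·male + β_smoker·smoker` (defaults
  α = −0.25, β_age = log(1.07)/yr, β_male = log 2, β_smoker = log 1.5)
  drives a binary `latent_high` outcome and a correlated self-reported
  health status. Per-record probabilities are kept in the truth ledger,
  so parameter recovery can be asserted: the survey-logistic 95% CI
  covers the true age OR in well over 90% of replicate cohorts.
  **Marker loadings on the latent predictor default to zero**, so the
  realized biomarker covariance is exactly the configured matrix (this is
  what makes the diagonal-covariance and quartile-prevalence properties
  exact); simulations that need behavior-linked physiology set the
  loadings explicitly.
* **Missingness** is MCAR per column, never touching design columns —
  complete-case filtering is the analysis behavior under test, and
  informative missingness is out of scope.

What the generator does **not** emulate: the real sampling frame and
oversampling fractions, skewed biomarker shapes (CRP and TG are heavy-
tailed in reality; truncated normal here), measurement error, or
missingness that depends on health. Passing tests therefore demonstrate
the correctness of the estimators and the pipeline mechanics under a
known design — not that any substantive finding about real cohorts
transfers.

## Numerical and reproducibility choices

* One run seed governs a pipeline; stage seeds are derived from it by
  hashing the stage label, so stages are isolated but the whole bundle is
  byte-identical under a fixed config + seed (asserted in the tests; the
  run log is excluded as it carries wall-clock timings).
* Ties in the rank-sum test share the mid-CDF score of their value
  group; quantile ties resolve by the left-inclusive convention.
* IRLS starts at β = 0; the information matrix is solved directly
  (Cholesky via `solve`), with singularity reported at the failing
  iteration.
* Simulation sizes in the test suite — 2000 replicates for test size,
  200 for CI coverage and factor-number calibration, 60-replicate
  medians for classical-oracle agreement — were chosen to keep
  Monte-Carlo error well inside the asserted bands at a few minutes of
  runtime.

## Limitations

The estimators cover the stratified two-stage linearization path only:
no replicate weights (jackknife/BRR), no domain estimation beyond the
two-level risk grouping, no finite-population corrections. The
comparison matrix operationalizes "better predictor" as
"significantly associated at α with that index's risk class by the
stated test" — a head-to-head superiority test is deliberately not
invented. AIC values are internal to this package's normalization. Real
survey extracts bring harmonization problems (variable names, units —
e.g. published albumin summaries are not always in conventional g/dL)
that are left to the user: values are taken as-is, never converted.
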