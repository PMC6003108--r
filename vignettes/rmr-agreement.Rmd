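---
title: "Agreement analysis of RMR prediction equations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agreement analysis of RMR prediction equations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmragree)
```

Resting metabolic rate (RMR, kcal/day) can be measured by indirect
calorimetry or predicted from anthropometrics. This vignette documents the
statistical machinery the package uses to quantify how well the classical
prediction equations agree with calorimetry, which subject factors drive
their errors, and how a BMI-class-based alternative equation is derived —
together with every tunable parameter, numerical choice and known
limitation.

## The agreement statistics

For paired per-subject measured (RMRm) and estimated (RMRe) values:

* **Mean bias** is the mean of individual differences RMRe − RMRm; positive
  values mean the equation overestimates. Its 95% confidence interval uses
  the t distribution, mean ± t₀.₉₇₅,ₙ₋₁ · sd/√n. At n ≈ 380 the t and
  normal intervals are indistinguishable; t is used so the same code is
  exact on small fixtures.
* **Absolute bias** is |mean(RMRm) − mean(RMRe)|, and **accuracy**
  (percentage deviation) is absolute bias × 100 divided by a group mean.
  Both denominators — the measured mean and the estimated mean — are
  defined in the literature, so `summarize_agreement()` reports both;
  `adequacy_flag()` requires *strictly* less than the threshold (default
  10%) in both directions.
* **N within 10%** counts subjects whose individual percentage deviation
  |RMRe − RMRm| × 100 / RMRm is ≤ 10. We read this count as a per-subject
  tally (the boundary value 10.0 counts), the natural reading of the
  summary-table convention it mirrors.

A deliberate subtlety: the absolute bias of the *group* equals
|mean bias| computed on the same subjects, and the test suite asserts that
identity; published tables rounded their means first, so recomputing their
bias column from rounded means can differ by a few kcal.

## The equation library

Equations live in an editable YAML file
(`system.file("extdata", "equations.yaml", package = "rmragree")`), not in
code: published variants of the same equation differ in minor digits, and a
config file makes the exact coefficients auditable and swappable. Each
equation is a set of per-(gender, age-bracket) linear rows
`intercept + w·W + h·H + a·A + b·BMI` in kcal/day. Height is canonically
stored in metres; rows declare `height_unit: cm` where the source equation
used centimetres, and the conversion is internal — a single canonical unit
prevents silent 100× errors.

Age brackets are inclusive integer ranges validated to tile ages 10–120
with no gap or overlap per gender; at a shared boundary the lower bracket
wins (age 18 uses the 10–18 row, age 30 the 19–30 row), a deterministic
tie-break. The Schofield and FAO/WHO/UNU rows are the 1985 report values,
with the reports' own 10–18 rows serving the adolescent subgroup. The
abbreviated Harris–Benedict rule is 24.0 (men) / 22.8 (women) kcal per kg
per day. The Harrington equation (BMI, age, gender) ships as a declared
placeholder with no coefficient rows — its coefficients are not publicly
tabulated, and inventing them would corrupt the comparison — so
`predict_all()` yields an all-`NA` column for it with a warning and every
downstream stage skips it.

## Bias-factor modelling

Individual absolute biases |RMRe − RMRm| are strongly right-skewed, so they
are first normalised with a Box-Cox power transform. λ is estimated per
equation by profile maximum likelihood on the grid [−1, 1.5] in steps of
0.01 (`MASS::boxcox`); typical absolute-bias values land between λ = 0
(log) and λ = 0.5 (square root). A constant vector has no defined λ and is
rejected as degenerate.

The transformed bias is then modelled as a main-effects linear model in
three categorical factors — gender, BMI class (codes 1–5) and age group —
with **backward elimination**: at each step the factor with the largest
whole-factor F-test p-value (via `drop1`) above α = 0.05 is removed, one
factor per step, ties broken in the fixed order gender → BMI class → age
group. Whole-factor tests (not per-dummy t tests) are used because the
scientific question is whether the factor as a whole matters. Reference
levels are the first level of each factor (female, normal weight, ages
10–18); this affects coefficient signs only, not p-values or the
main-effects profiles. Factor levels with fewer than two observations are
collapsed into the adjacent level with a warning, and a factor aliased with
another (possible in tiny designed fixtures) is treated as removable first.
Interactions are deliberately out of scope: the target analysis is a
main-effects one.

## Cross-tabulations

`crosstab_test()` tabulates gender, age group or education against BMI
classes 1–5 (underweight subjects, and unknown-education subjects for the
education table, are excluded) and applies Pearson's chi-square without
continuity correction — the primary tables are r×5, not 2×2. Cells are
flagged when the standardized residual (O − E)/√E exceeds |2|; adjusted
residuals (further divided by √((1−row prop)(1−col prop))) are available
via `residual_type = "adjusted"` but are not the default, matching the
|2| rule-of-thumb convention. The statistic equals the sum of squared
standardized residuals, an identity the tests assert. Expected counts below
1 attach a validity warning rather than an error.

## The BMI-class power-law equation

Per-kg measured RMR declines with BMI class. `class_means()` computes the
class means of RMRm/weight (kcal/kg/day) with t confidence intervals, and
`fit_power_law()` regresses log₁₀(class mean) on log₁₀(k) where **k is the
integer class code 1–5, not raw BMI**. The class-code regressor is the
canonical mode because it is the only reading under which the published
per-class means reproduce the published coefficients with R² near 99%; a
raw-BMI regressor and a subject-level (rather than class-mean) fit are
provided as clearly-labelled non-canonical sensitivity modes. The fitted
power form is RMR (kcal/kg/day) = c·k^b with c = 10^intercept, and
`predict_new_equation()` scales by body weight. The response unit follows
the per-kg convention of the class-means table; the equation's reliability
is at the *group* (class) level, not for individual prediction. Class 0
(underweight) is outside the fitted domain and is rejected.

## The synthetic-cohort generator

No subject-level data are distributable, so `generate_cohort()` draws
cohorts with the structure the analysis assumes: 105 men and 278 women;
age, weight and height from gender-specific truncated normals matching the
target population's published moments and ranges (e.g. male weight
100.1 ± 23.1 kg on [59, 177]); measured RMR from the gendered per-kg power
laws (men 25.41·k^−0.2115, women 21.09·k^−0.1786 kcal/kg/day) with
multiplicative lognormal noise.

Choices the marginals alone do not determine, fixed once:

* **Weight–height coupling**: a Gaussian copula with ρ = 0.4 within gender,
  a realistic anthropometric correlation, so that BMI (and hence the class
  distribution) has believable spread rather than the inflated variance
  independence would give.
* **Noise**: σ = 0.04 log₁₀ units (~9.6% CV) of multiplicative noise on
  RMRm — a tuning default chosen so simulated per-equation accuracies span
  the few-percent-to-25% range observed in practice, not a published value.
* **Education**: sampled from (0.25, 0.45, 0.30) over
  primary/secondary/tertiary with a 1.5× odds tilt toward tertiary in the
  normal-weight class; the direction mirrors the well-replicated
  education–BMI gradient, the magnitude is synthetic.
* Underweight draws (rare) use class code 1 in the RMR model, since code 0
  would be degenerate; those subjects are excluded from every statistic
  anyway. Truncated-normal draws use the inverse-CDF transform, which keeps
  the generator deterministic given a seed.

What passing tests on synthetic cohorts do **not** show: the generator has
no body-composition structure (fat-free mass is the physiological driver
the power law only proxies), no seasonal or device effects, exact
power-law-in-class-code truth (real per-kg RMR varies within class), and
independence of age from weight. Results on real cohorts can differ in all
of those directions; the synthetic pipeline demonstrates statistical
correctness and parameter recovery, not clinical validity.

## Problem sizes and reproducibility

The bundled tests run the generator at the study size (n = 383) and, for
distributional checks, n = 10⁴; parameter-recovery averages 100 seeded
replicates; the null simulation for the elimination procedure uses 1000
replicates at n = 150; Monte-Carlo oracles (permutation chi-square,
bootstrap CI) use 10⁴ draws. All randomness flows from explicit seeds, and
`run_pipeline()` records its seed in the run log so any report bundle can
be regenerated byte-identically.

## Known limitations

* The Harrington placeholder means category 5 (BMI-based) equations are
  compared only through published summary statistics, not re-evaluated per
  subject.
* The within-10% count is a per-subject reading of a terse convention; a
  bootstrap-count reading would differ.
* Backward elimination's per-factor type-I error is only approximately α —
  selection among three factors distorts it slightly, which the acceptance
  test brackets with a Monte-Carlo-aware band rather than asserting
  equality.
* The package targets ages ≥ 10 and has no paediatric or body-composition
  support.
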