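# rmragree

Method-comparison analysis of resting metabolic rate (RMR) prediction
equations against indirect-calorimetry measurements, for nutrition and
clinical-metabolism researchers who need to know *which* prediction equation
to trust for a given population — and how body composition class distorts
each one.

## What it computes

Given a cohort with measured RMR (kcal/day) and anthropometrics, the package
evaluates a library of classical prediction equations (Harris–Benedict 1919
and its Roza–Shizgal revision, the abbreviated per-kg Harris–Benedict rule,
Mifflin–St Jeor, Owen, Schofield, and the FAO/WHO/UNU weight-only and
weight+height forms) and reports, per equation:

- **mean bias** = mean(RMRe − RMRm), with a 95% t confidence interval on the
  mean of individual biases (positive = overestimation);
- **absolute bias** = |mean(RMRm) − mean(RMRe)|;
- **accuracy** (percentage deviation) = absolute bias × 100 / mean, against
  both the measured and the estimated mean — below 10% is conventionally
  adequate;
- **N within 10%** = the number of subjects whose individual
  |RMRe − RMRm| × 100 / RMRm is at most 10.

Around that core it provides:

- a regression of Box-Cox-normalised individual absolute bias on gender, WHO
  BMI class and age group, with whole-factor backward elimination — which
  factor drives each equation's disagreement;
- Pearson chi-square cross-tabulations of BMI classes against gender, age
  group and education, flagging cells with standardized residuals
  (O − E)/√E beyond |2|;
- the **BMI-class power-law RMR equation**: ordinary least squares of
  log₁₀(mean RMR per kg body weight) on log₁₀(BMI-class code k = 1…5),
  giving RMR (kcal/kg/day) = c·k^b with c = 10^intercept — fitted overall
  and per gender;
- a synthetic-cohort generator (truncated-normal anthropometrics, gendered
  per-kg power-law RMR with lognormal noise) so the entire pipeline is
  testable without subject-level data.

## Worked example

```r
library(rmragree)

cohort <- generate_cohort(seed = 42)          # 383 subjects, 105 M / 278 F
pred   <- predict_all(cohort, default_equations())
tab    <- agreement_table(pred, cohort)
tab[, c("equation", "mean", "mean_bias", "accuracy_vs_m", "n_within_10")]
#>    equation mean mean_bias accuracy_vs_m n_within_10
#> 1      RMRm 1638        NA            NA          NA
#> 2       H-B 1707     69.00         4.212         216
#> 3   H-B_Rev 1693     54.58         3.332         225
#> 4   Mifflin 1608    -29.63         1.809         236
#> 5      FWU1 1725     86.61         5.287         211
#> 6      FWU2 1737     98.49         6.013         200
#> 7 Schofield 1719     81.00         4.945         205
#> 8      Owen 1531   -106.56         6.505         212
#> 9  H-B_Abbr 2020    381.83        23.310          78
```

The per-kg abbreviated Harris–Benedict rule overestimates this cohort by
~380 kcal/day (23% deviation — far beyond the 10% adequacy rule), while the
full covariate equations sit within 2–7%. Fitting the BMI-class power law:

```r
fit <- fit_power_law(cohort)
fit
#> <power_law_fit> RMR (kcal/kg/day) = 21.89 * (class)^-0.1568  [both]
#>   log10(RMR) = 1.34 -0.1568 log10(class);  R2 = 99.4%  (5 class-mean points)

predict_new_equation(fit, bmi_class = 2, weight_kg = 80)
#> [1] 1570.779    # kcal/day for an 80 kg overweight subject
```

Per-kg RMR declines with BMI class (heavier bodies burn fewer kcal per kg at
rest), and the fitted exponent quantifies that decline. `run_pipeline()`
writes all report tables (agreement, bias-model, class means, power-law
fits, cross-tabulations) as CSV plus a seeded run log.

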