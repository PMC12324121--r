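# trionurture

Trio Mendelian randomization of parental BMI effects on offspring
adiposity and diet, with a synthetic trio-cohort simulator for validation.

## The problem

Parental and child BMI are correlated, but ordinary regression cannot say
whether that reflects a causal effect of the parental phenotype (*genetic
nurture* — parents shaping the child's food environment) or simply the
alleles the child inherited (*direct genetic effects*). `trionurture`
implements the within-family instrumental-variables design that separates
them in mother–father–child trios:

- each parent's BMI is instrumented by their polygenic index (PGI),
  a standardized weighted sum of effect-allele dosages,
  `PGI_i = sum_j beta_j g_ij`;
- the model conditions on the **child's** PGI (blocking the transmitted
  alleles) and includes **both** parents' PGIs (blocking the path opened
  by assortative mating and the collider opened by conditioning on the
  child's PGI);
- estimation is weighted two-stage least squares with
  heteroskedasticity- or cluster-robust sandwich errors and first-stage
  partial-F diagnostics, `beta_IV = (X'P_Z X)^{-1} X'P_Z y` in the
  weighted metric.

Alongside the MR model the package fits the standard phenotypic
multivariable regression (no child PGI), a three-PGI decomposition whose
mother/child coefficient ratio measures indirect relative to direct
genetic effects, linear probability models for dichotomized diet items,
inverse-probability non-response weights, and Rao–Wu rescaling bootstrap
confidence intervals for MR-versus-phenotypic coefficient contrasts under
stratified clustered survey designs. Outcome preparation covers LMS
(Box–Cox) BMI z-scores against a growth reference, single-pass 3-SD
outlier trimming, and a multiple-correspondence-analysis diet factor.

Because the cohort data this design targets are access-restricted, the
package ships a fully parameterized synthetic trio simulator
(`sim_config()` / `simulate_trio_cohort()`) with Mendelian transmission,
phenotypic assortative mating, genetic nurture, parental self-report
error, survey design fields and BMI-dependent attrition. Every estimator
is validated by parameter recovery against the simulator's known truth.

## Worked example

Simulate a cohort of 2,600 trios under the default calibration (spousal
BMI correlation 0.21, maternal nurture effect 0.32 kg/m² at age 17,
null paternal effect), build PGIs, and fit the age-17 models:

```r
library(trionurture)

cfg    <- sim_config(n_families = 2600, n_snps = 500, seed = 1)
cohort <- simulate_trio_cohort(cfg)
pgi    <- build_pgi(cohort)

fit_trio_mr(cohort, "bmi", sweep = 17, pgi)
#> trio_model [mr], n = 2213
#>               estimate     se  ci_low ci_high
#> mother_bmi      0.2800 0.0546  0.1729  0.3870
#> father_bmi     -0.0577 0.0548 -0.1651  0.0497
#> pgi_child       1.1320 0.0737  0.9874  1.2765
#> ...
#> first-stage partial F: mother_bmi = 64.8, father_bmi = 58.0

round(coef(fit_phenotypic_model(cohort, "bmi", sweep = 17))[1:2], 4)
#> mother_bmi father_bmi
#>     0.3360     0.0417

dec <- fit_pgi_model(cohort, "bmi", 17, pgi)
sprintf("indirect/direct ratio: %.2f (SE %.2f)", dec$ratio$estimate, dec$ratio$se)
#> "indirect/direct ratio: 0.28 (SE 0.07)"
```

Reading the output: a +1 kg/m² difference in the mother's BMI causes a
0.28 kg/m² (95% CI 0.17–0.39) higher child BMI at 17 in the MR model —
close to the generative truth of 0.32 — while the father's MR estimate is
compatible with zero even though his *phenotypic* coefficient (0.042 per
kg/m², and strongly "significant" at large n) is inflated by the alleles
he transmitted. Both instruments are strong (partial F ≈ 58–65). The
three-PGI model attributes to the mother's PGI about 28% of the direct
(child-PGI) effect, inside the 0.25–0.50 band such decompositions report.

`run_full_analysis()` orchestrates trimming → z-scores → MCA diet factor →
non-response weights → all requested models across sweeps into a tidy
results table; `run_recovery_experiment()`, `run_bias_demo()` and
`run_null_calibration()` are the replication harnesses used by the tests.

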