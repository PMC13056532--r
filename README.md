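# maihda

Intersectional **MAIHDA** (multilevel analysis of individual heterogeneity
and discriminatory accuracy) for lifestyle-behaviour strata and body-mass
outcomes, for epidemiologists who want to ask how much of the variation in
BMI or obesity risk lies *between* combinations of lifestyle behaviours, and
whether any combination carries a multiplicative effect beyond the sum of
its parts.

Five guideline-adherence codes — sleep 7–9 h/day, ≥5 fruit-and-vegetable
portions/day, ≤14 alcohol units/week, ≥150 min moderate or ≥75 min vigorous
activity/week, and smoking status (previous/current/never) — define
2×2×2×2×3 = 48 strata keyed by 5-digit codes such as `"01112"`. Individuals
(level 1) are nested in strata (level 2) and a sequence of random-intercept
models is fitted per sex:

- **Model 1 (null):** `y_ij = β0 + u_j + e_ij`, `u_j ~ N(0, σ²_u)`
- **Model 2:** + fixed effects of the five behaviours
- **Model 3:** + confounders (age and Townsend Deprivation Index centred at
  their means, ethnicity, employment)

with the logistic analogue `logit π_ij = x'β + u_j` for the obesity-vs-normal
and overweight-vs-normal contrasts. The fits yield

- **VPC** = 100·σ²_u/(σ²_u + σ²_e), the share of variance between strata
  (logistic denominator fixed at the latent-scale constant π²/3 ≈ 3.29);
- **PCV**, the proportional reduction in σ²_u relative to the null model —
  large PCV means additive main effects dominate;
- empirical-Bayes (shrunken) per-stratum predictions with and without the
  random intercept, ranked tables of the lowest/highest five strata, and an
  interaction flag wherever the two 95% intervals are strictly disjoint.

The linear models are fitted by REML (profiled likelihood over
σ²_u/σ²_e), the logistic models by adaptive Gauss–Hermite quadrature; both
estimators live in this package and are cross-checked against closed forms,
dense numerical integration and lme4 in the test suite. A synthetic-cohort
generator with known ground truth (additive behaviour effects, latent
stratum deviations, injectable interaction offsets, raw questionnaire
measures that recode back to the drawn adherence codes exactly) makes the
whole pipeline testable without any restricted data access.

## Worked example

```r
library(maihda)

cfg    <- synthetic_config(n_per_sex = 50000, seed = 42)
cohort <- generate_cohort(cfg)
raw    <- emit_raw_questionnaire(cohort)        # raw questionnaire scales
report <- run_maihda(maihda_config(raw, outcome = "bmi", sexes = "male"))
print(report)
#> MAIHDA report: 1 analysis cell(s)
#>   male:bmi: n = 49555; VPC% by model: 1=4.46, 2=0.00, 3=0.00

print(report$cells[["male:bmi"]]$summary, digits = 3)
#>   model sigma2_u sigma2_e vpc_pct pcv_pct  loglik boundary
#> 1     1    0.656     14.1    4.46       0 -135873    FALSE
#> 2     2    0.000     14.1    0.00     100 -135815     TRUE
#> 3     3    0.000     14.1    0.00     100 -135826     TRUE
```

Reading the output: in the null model 4.46% of BMI variance lies between
the 48 behaviour combinations (σ²_u = 0.656 against a within-stratum
σ²_e = 14.1 (kg/m²)²). Adding the five behaviour main effects absorbs all
of it (PCV = 100%, boundary fit σ²_u = 0) — exactly what a purely additive
cohort should show, and the signature that distinguishes additive from
multiplicative behaviour effects in real data. The ranked stratum table
shows never/current smokers who meet the activity and sleep guidelines at
the bottom of the BMI scale:

```r
rank_strata(report$cells[["male:bmi"]]$predictions)$lowest[, 1:5]
#>   stratum    n observed incl_est incl_lower
#> 1   10112 2689     26.9     26.9       26.9
#> 2   10111  621     26.8     26.9       26.8
#> 3   11112  974     26.9     27.0       26.9
#> 4   11111  245     27.0     27.0       26.9
#> 5   10012 7901     27.3     27.2       27.2
```

To probe the interaction machinery, inject a +2 kg/m² offset into one
stratum and re-run: `inject_stratum_interaction(cfg, "11112", 2.0)` — the
flag for `"11112"` is raised by confidence-interval non-overlap in the
`flag_interactions()` output.

A thin command-line wrapper is installed with the package:

```sh
Rscript inst/scripts/maihda simulate --seed 4 --out cohort.csv
Rscript inst/scripts/maihda run --input cohort.csv --outcome bmi --sex male --outdir out
```

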