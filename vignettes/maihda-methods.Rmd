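---
title: "Intersectional MAIHDA for lifestyle strata: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intersectional MAIHDA for lifestyle strata: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maihda)
```

## The question the method answers

Five lifestyle behaviours — sleep duration, fruit-and-vegetable intake,
alcohol intake, physical activity and smoking — are each covered by a UK
public-health recommendation. Binary adherence codes for the first four
(sleep 7–9 h/day; at least 5 portions/day; at most 14 units/week; at least
150 min moderate or 75 min vigorous activity/week) and a three-level smoking
status (previous / current / never) define 2×2×2×2×3 = 48 mutually exclusive
*strata*, identified by a 5-digit key in the fixed digit order (sleep,
fruit&veg, alcohol, activity, smoking); `"01112"`, for instance, is a never
smoker who met everything except the sleep guideline.

MAIHDA (multilevel analysis of individual heterogeneity and discriminatory
accuracy) asks two questions about these strata and an outcome such as BMI
or obesity: *how much* of the outcome variance lies between strata rather
than between individuals within strata, and whether a stratum's outcome
deviates from the *sum* of its component behaviour effects — an additive
vs multiplicative (interaction) decomposition.

## Models

Individuals $i$ are nested in strata $j$. The linear sequence for BMI is

$$\text{Model 1 (null):}\quad y_{ij} = \beta_0 + u_j + e_{ij}, \qquad
u_j \sim N(0, \sigma^2_u),\; e_{ij} \sim N(0, \sigma^2_e)$$

Model 2 adds fixed effects for the five behaviour codes used to build the
strata; Model 3 further adds confounders (age and Townsend Deprivation
Index, each centred at its mean within the analysed sex; ethnicity;
employment). For binary weight-status contrasts (obesity vs normal weight,
overweight vs normal weight) the same sequence runs as a random-intercept
logistic model, $\mathrm{logit}\,\pi_{ij} = x_{ij}'\beta + u_j$.

Two derived quantities summarise the decomposition:

* **VPC** $= 100\,\sigma^2_u/(\sigma^2_u + \sigma^2_e)$. On the logistic
  latent scale the individual-level variance is not estimated and is fixed
  at the standard-logistic variance $\pi^2/3 \approx 3.29$
  (`logistic_latent_variance()`).
* **PCV**, the proportional change in between-stratum variance relative to
  the null model. `compute_pcv()` returns the *positive reduction*
  convention, $100(\sigma^2_{u,\text{null}} -
  \sigma^2_{u,\text{model}})/\sigma^2_{u,\text{null}}$, so that "92.9%
  explained by additive effects" reads positively; an increase in variance
  yields a negative value carrying an `increased` attribute.

Per-stratum results are empirical-Bayes (shrunken) predictions. The fit
produces, for each stratum, the prediction *excluding* the random intercept
(fixed part only, averaged over the stratum's member covariate rows, on the
probability scale through the inverse link for logistic fits) and the
prediction *including* it (the empirical-Bayes intercept added on the
linear-predictor scale before the link). A stratum whose two 95% intervals
are strictly disjoint — compared on unrounded values — is flagged as showing
a multiplicative effect. Strata are ranked ascending by the including-RE
prediction, ties broken by key, and the five lowest/highest reported.

## Estimation

Both mixed models are estimated by the package itself; general-purpose
mixed-model software (lme4) appears only as an independent cross-check in
the test suite.

**Linear.** With a single grouping factor the covariance is block diagonal,
so the REML (default) or ML criterion profiles down to a one-dimensional
function of the variance ratio $\psi = \sigma^2_u/\sigma^2_e$, computed from
per-stratum sufficient statistics in $O(n)$. The optimum over $\log\psi$ is
bracketed by a golden-section/parabolic search and then polished to machine
precision by root-finding on the analytic derivative of the profiled
criterion. If the criterion is minimised at $\psi \to 0$ (i.e. the
between-group mean square falls below the within-group mean square) the
estimate is truncated at $\sigma^2_u = 0$ and flagged as a boundary fit. On
balanced designs the result equals the one-way ANOVA closed form
($\hat\sigma^2_e = MS_w$, $\hat\sigma^2_u = (MS_b - MS_w)/m$), which the
tests verify to $10^{-6}$. Estimation is REML/ML rather than the IGLS of
older multilevel software; under normality these coincide (IGLS converges to
ML), and the difference is covered by the tolerances used throughout.

**Logistic.** Maximum likelihood with adaptive Gauss–Hermite quadrature
(default order 15): each stratum's integrand is centred at its posterior
mode and scaled by the curvature there (a Laplace step), then integrated
over the quadrature nodes. The marginal likelihood factorises over strata,
and rows sharing a stratum and an identical design row are collapsed to
binomial counts first — the null and main-effects models, whose covariates
are constant within stratum, therefore cost the same at $n = 10^5$ as at
$n = 10^3$. The score is computed from the posterior node weights (Fisher's
identity) and the optimiser is L-BFGS-B on $(\beta, \log\sigma_u)$ with
$\log\sigma_u$ bounded below; reaching the bound is reported as a
boundary fit with $\sigma^2_u = 0$. Wald inference is used throughout, and
odds-ratio intervals are exactly $\exp(\hat\beta \pm 1.96\,SE)$.
Coefficients whose standardized magnitude diverges (norm above 50, or any
single scaled coefficient above 25 — a log-odds shift no non-separated
binary fit can produce) raise a separation error rather than returning
garbage. Quadrature order 7 and order 31 agree on $\beta$ to well under
$10^{-4}$ in the tests, and the tests also check the posterior mode of a
stratum intercept against dense 1-D numerical integration.

**Shrinkage.** Linear empirical-Bayes intercepts are
$\hat u_j = \lambda_j(\bar y_j - \bar x_j'\hat\beta)$ with
$\lambda_j = \sigma^2_u/(\sigma^2_u + \sigma^2_e/n_j)$, with the conditional
posterior SD $\sqrt{\sigma^2_u(1 - \lambda_j)}$; logistic intercepts are
posterior modes with Laplace SDs. Empty strata are kept in every output
(their predictions use the fixed part at the decoded behaviour codes with
confounders at their centring values, and the prior SD $\sqrt{\sigma^2_u}$)
— handling thin strata gracefully is precisely what the precision-weighted
multilevel formulation buys.

### Interval approximations

The excluding-RE interval is Wald on the averaged linear predictor using the
fixed-effect covariance; the including-RE interval adds the posterior
variance of $\hat u_j$ and ignores the covariance between the fixed and
random parts. Logistic intervals are built on the logit scale around the
logit of the averaged probability and inverse-linked, which keeps them
inside $[0,1]$ and containing their point estimate. These are documented
approximations, not exact posterior intervals, and the interval-non-overlap
interaction rule built on them is deliberately conservative: the package
reports flags, not calibrated p-values.

## The exclusion cascade and diagnostics

`apply_exclusions()` drops records in a fixed order, each record counted
under the first applicable reason: missing lifestyle codes → missing
confounders → missing BMI → underweight (BMI < 18.5, excluded because such
cohorts contain too few underweight adults to model) → the weight category
outside a binary contrast. The ledger satisfies
input = retained + Σ reasons by construction, and permuting the input rows
never changes it. Weight status uses half-open intervals with the 30.0
boundary classified obese (the categories as printed in descriptive tables
— "25.0–29.9" and ">30" — leave 29.9–30.0 ambiguous; half-open intervals
are the standard convention that partitions the axis). The alcohol boundary
is inclusive (14 units meets "no more than 14") as are both sleep boundaries
(7 and 9 meet "7–9 h"). The activity rule is a logical OR of the two
thresholds; no combined moderate+vigorous equivalence score is computed,
because the recommendations are stated as two separate thresholds.
Complete-case analysis only; no imputation.

`collinearity_diagnostics()` reports pairwise correlations and
$VIF_k = 1/(1 - R^2_k)$ per predictor; exactly collinear columns get an
infinite VIF and a flag.

## What the synthetic generator emulates — and what it does not

`synthetic_config()` defaults describe a large UK adult cohort:

| parameter | default | meaning |
|---|---|---|
| behaviour prevalences | per sex, e.g. male smoking 40.5/11.2/48.3% previous/current/never | adherence rates of each guideline |
| behaviour effects | per sex, kg/m²; e.g. male activity −1.08, never-smoking −0.99 | additive BMI shift for meeting each guideline (confounder-adjusted main effects) |
| intercept | 29.82 (m) / 28.60 (f) kg/m² | reference profile: nothing met, previous smoker |
| `residual_sd_bmi` | √15.15 kg/m² | within-stratum individual SD |
| `extra_stratum_sd` | 0 | latent stratum deviation beyond additivity |
| `interaction_offsets` | none | injected multiplicative effects, kg/m² |
| confounder effects | 0 | confounders are drawn but inert by default, since adjusting for them changes the variance decomposition little |

Behaviour codes are drawn *independently* across behaviours (only marginal
prevalences are emulated; real behaviours cluster, which is why the
defaults imply a null-model linear VPC near the low end, ≈ 3.5–4.5%, of the
4–7% such cohorts show). Raw questionnaire values are drawn uniformly
within the code-consistent range (e.g. sleep-meeting hours ~ U[7, 9]) —
the simplest distribution that makes guideline recoding reproduce the drawn
codes exactly, which the tests verify record by record. BMI is the additive
sum plus Gaussian noise; obesity is BMI ≥ 30 by default
(`threshold-on-BMI`), keeping the linear and logistic pipelines coherent on
one cohort, with an `independent-logit` mode (outcome drawn from
$\mathrm{logit}\,\pi_j = \beta_0 + u_j$ with a user-set latent
$\sigma_u$) for logistic-only recovery studies. One integer seed governs a
single documented draw stream (per sex: codes, stratum offsets,
confounders, BMI noise, raw measures, then the latent-logit outcome), so
cohorts are byte-identical across runs.

Not emulated: sampling design and non-response, measurement error, recall
bias, behaviour–behaviour correlation, longitudinal structure, and the
right-skew of real BMI (the generator is Gaussian within stratum). Passing
tests therefore demonstrate that the estimators recover the structure this
generative model encodes — they do not validate the substantive
epidemiology of any real cohort.

## Problem sizes and empirical checks

The test-suite simulations use cohorts of 100,000 per sex for calibration
and recovery checks, 10 replicates for variance-component recovery
(between-stratum 0.70 against within 15.15 linear; latent 0.25 logistic),
and 20 replicates for the interaction-detection study, where a +2 kg/m²
offset injected into stratum `"11112"` must be flagged by interval
non-overlap while purely additive cohorts must produce almost no flags.
Smaller sizes (2,000–20,000 per sex) are used where only invariances are
being exercised. `scripts/acceptance.R` re-runs the full set of headline
quantities from scratch at these sizes.

## Known limitations

* Wald-only inference; no profile-likelihood or bootstrap intervals.
* The fixed–random covariance omitted from prediction intervals slightly
  narrows them for large strata.
* The interaction flag's error rate is not calibrated; treat it as a
  screening rule.
* No multinomial model over the full weight-status scale: the two binary
  contrasts run separately (a multinomial version is prone to convergence
  trouble at these stratum counts).
* Estimation differences from IGLS/MCMC-based multilevel software are
  expected at the third decimal, not the first.
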