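# Independent oracles and small fixture builders used across the suite.

# Balanced one-way ANOVA closed form for the random-intercept linear model:
# sigma2_e = MS_within, sigma2_u = (MS_between - MS_within) / n_per_group.
anova_oracle <- function(y, groups) {
  g <- split(y, groups)
  stopifnot(length(unique(lengths(g))) == 1L)
  m <- lengths(g)[1]
  means <- vapply(g, mean, numeric(1))
  ms_within <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1))) /
    (length(y) - length(g))
  ms_between <- m * sum((means - mean(y))^2) / (length(g) - 1)
  list(beta0 = mean(y), sigma2_e = ms_within,
       sigma2_u = max((ms_between - ms_within) / m, 0))
}

# Dense 1-D numerical integration oracle for the posterior of a single
# stratum's random intercept in the logistic model.
posterior_mode_grid <- function(y_str, eta_str, sigma2_u,
                                grid = seq(-4, 4, by = 1e-4)) {
  lp <- vapply(grid, function(u) {
    eta <- eta_str + u
    sum(y_str * eta - log1p(exp(eta))) - u^2 / (2 * sigma2_u)
  }, numeric(1))
  grid[which.max(lp)]
}

# Intercept-only design with a named column, as most toy fits need.
intercept_design <- function(n) matrix(1, n, 1,
                                       dimnames = list(NULL, "intercept"))

# A fully coded record with sensible defaults, for exclusion-cascade tests.
coded_record <- function(sex = "male", sleep = 1L, fv = 1L, alcohol = 1L,
                         pa = 1L, smoking = 2L, age = 55, tdi = -1.5,
                         ethnicity = "white", employment = "employed",
                         bmi = 24) {
  data.frame(sex = sex, sleep_meets = sleep, fv_meets = fv,
             alcohol_meets = alcohol, pa_meets = pa, smoking_code = smoking,
             age = age, tdi = tdi, ethnicity = ethnicity,
             employment = employment, bmi = bmi,
             weight_status = if (is.na(bmi)) NA_character_
                             else classify_weight_status(bmi),
             stringsAsFactors = FALSE)
}

# Male analysis set of a generated cohort: coded records, stratum factor.
male_analysis_set <- function(cohort, contrast = "bmi-linear") {
  coded <- recode_behaviours(emit_raw_questionnaire(cohort))
  ex <- apply_exclusions(coded[coded$sex == "male", , drop = FALSE], contrast)
  idx <- assign_strata(ex$data)
  list(data = ex$data, ledger = ex$ledger, index = idx,
       f = attr(idx, "assignment"))
}
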