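# Synthetic cohort generator.
#
# Emulates the structure the analysis assumes: guideline-adherence behaviour
# codes drawn independently per person from sex-specific prevalences, BMI
# built additively from per-behaviour effects plus an optional latent
# stratum-level deviation and injected stratum-specific interaction offsets,
# and raw questionnaire-scale measures drawn so that guideline recoding
# reproduces the drawn codes exactly.

default_behaviour_prevalences <- function() {
  list(
    male = list(sleep = 0.755, fv = 0.272, alcohol = 0.249, pa = 0.821,
                smoking = c(previous = 0.405, current = 0.112, never = 0.483)),
    female = list(sleep = 0.771, fv = 0.385, alcohol = 0.479, pa = 0.832,
                  smoking = c(previous = 0.355, current = 0.080, never = 0.565))
  )
}

default_behaviour_effects <- function() {
  # Additive BMI shifts (kg/m^2) for meeting each guideline (reference:
  # not meeting; smoking reference: previous smoker).
  list(
    male = c(sleep = -0.64, fv = 0.10, alcohol = -0.31, pa = -1.08,
             smoking_current = -0.93, smoking_never = -0.99),
    female = c(sleep = -0.56, fv = -0.39, alcohol = 0.17, pa = -1.50,
               smoking_current = -0.50, smoking_never = -0.44)
  )
}

default_confounder_distributions <- function() {
  list(
    male = list(age = c(mean = 56.7, sd = 8.0), tdi = c(mean = -1.6, sd = 2.9),
                white = 0.933, employed = 0.631),
    female = list(age = c(mean = 55.7, sd = 7.9), tdi = c(mean = -1.7, sd = 2.7),
                  white = 0.924, employed = 0.601)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a large UK adult cohort: behaviour prevalences and
#' confounder distributions from published descriptive statistics, and
#' additive per-behaviour BMI effects from the confounder-adjusted
#' main-effects model.
#'
#' @param n_per_sex Number of records per sex.
#' @param behaviour_prevalences Per-sex list of adherence probabilities for
#'   `sleep`, `fv`, `alcohol`, `pa` and a 3-vector `smoking`
#'   (previous/current/never) summing to 1.
#' @param behaviour_effects_bmi Per-sex named vector of additive BMI shifts
#'   (kg/m^2): `sleep`, `fv`, `alcohol`, `pa` (meeting vs not) and
#'   `smoking_current`, `smoking_never` (vs previous).
#' @param confounder_distributions Per-sex list: `age` and `tdi` as
#'   `c(mean=, sd=)`, plus probabilities `white` and `employed`.
#' @param confounder_effects_bmi Named vector `age`, `tdi` (per unit, centred
#'   at the configured means), `nonwhite`, `notemployed`; defaults all zero.
#' @param intercept_bmi Per-sex BMI intercept (kg/m^2) at the reference
#'   profile (nothing met, previous smoker, mean age/TDI, white, employed).
#' @param residual_sd_bmi Within-stratum (individual) BMI SD, kg/m^2.
#' @param extra_stratum_sd SD (kg/m^2) of a latent stratum-level deviation
#'   beyond the additive effects; 0 makes the generative model purely additive.
#' @param interaction_offsets Named numeric vector mapping stratum keys to
#'   additional BMI offsets (kg/m^2) — injected multiplicative effects.
#' @param obesity_rule `"threshold-on-BMI"` (obese iff BMI >= 30, coherent
#'   with the linear outcome) or `"independent-logit"` (binary outcome drawn
#'   from a latent-scale logistic model, for logistic-only recovery studies).
#' @param logit_intercept,logit_sigma_u Latent-scale intercept and stratum SD
#'   used only under `obesity_rule = "independent-logit"`.
#' @param seed Integer seed governing all draws through one documented stream.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_sex = 1000,
                             behaviour_prevalences = default_behaviour_prevalences(),
                             behaviour_effects_bmi = default_behaviour_effects(),
                             confounder_distributions = default_confounder_distributions(),
                             confounder_effects_bmi = c(age = 0, tdi = 0,
                                                        nonwhite = 0,
                                                        notemployed = 0),
                             intercept_bmi = c(male = 29.82, female = 28.60),
                             residual_sd_bmi = sqrt(15.15),
                             extra_stratum_sd = 0,
                             interaction_offsets = numeric(0),
                             obesity_rule = c("threshold-on-BMI",
                                              "independent-logit"),
                             logit_intercept = log(1.11),
                             logit_sigma_u = 0.5,
                             seed = 1L) {
  obesity_rule <- match.arg(obesity_rule)
  cfg <- structure(
    list(n_per_sex = n_per_sex,
         behaviour_prevalences = behaviour_prevalences,
         behaviour_effects_bmi = behaviour_effects_bmi,
         confounder_distributions = confounder_distributions,
         confounder_effects_bmi = confounder_effects_bmi,
         intercept_bmi = intercept_bmi,
         residual_sd_bmi = residual_sd_bmi,
         extra_stratum_sd = extra_stratum_sd,
         interaction_offsets = interaction_offsets,
         obesity_rule = obesity_rule,
         logit_intercept = logit_intercept,
         logit_sigma_u = logit_sigma_u,
         seed = as.integer(seed)),
    class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  chk_prob <- function(p, nm) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
      stop_maihda("configuration error in field '", nm,
                  "': probabilities must lie in [0, 1]")
  }
  if (!is.numeric(cfg$n_per_sex) || cfg$n_per_sex < 1)
    stop_maihda("configuration error in field 'n_per_sex': must be >= 1")
  for (s in c("male", "female")) {
    bp <- cfg$behaviour_prevalences[[s]]
    if (is.null(bp)) stop_maihda("configuration error in field ",
                                 "'behaviour_prevalences': missing sex '", s, "'")
    for (b in c("sleep", "fv", "alcohol", "pa"))
      chk_prob(bp[[b]], paste0("behaviour_prevalences$", s, "$", b))
    chk_prob(bp$smoking, paste0("behaviour_prevalences$", s, "$smoking"))
    if (abs(sum(bp$smoking) - 1) > 1e-8)
      stop_maihda("configuration error in field 'behaviour_prevalences$", s,
                  "$smoking': level probabilities must sum to 1")
    cd <- cfg$confounder_distributions[[s]]
    chk_prob(cd$white, paste0("confounder_distributions$", s, "$white"))
    chk_prob(cd$employed, paste0("confounder_distributions$", s, "$employed"))
    if (cd$age[["sd"]] <= 0 || cd$tdi[["sd"]] <= 0)
      stop_maihda("configuration error in field 'confounder_distributions$",
                  s, "': SDs must be positive")
  }
  if (!is.finite(cfg$residual_sd_bmi) || cfg$residual_sd_bmi <= 0)
    stop_maihda("configuration error in field 'residual_sd_bmi': must be > 0")
  if (cfg$extra_stratum_sd < 0)
    stop_maihda("configuration error in field 'extra_stratum_sd': must be >= 0")
  if (length(cfg$interaction_offsets)) {
    for (k in names(cfg$interaction_offsets)) validate_stratum_key(k)
  }
  invisible(cfg)
}

#' Read a generator configuration from a YAML file
#'
#' Top-level YAML keys mirror the [synthetic_config()] arguments; omitted
#' keys keep their defaults. `interaction_offsets` is a mapping from stratum
#' key to BMI offset.
#'
#' @param path Path to a YAML file.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  scalar <- c("n_per_sex", "intercept_bmi", "residual_sd_bmi",
              "extra_stratum_sd", "obesity_rule", "logit_intercept",
              "logit_sigma_u", "seed")
  for (nm in intersect(names(raw), scalar)) args[[nm]] <- raw[[nm]]
  if (!is.null(raw$intercept_bmi) && length(raw$intercept_bmi) == 2)
    args$intercept_bmi <- unlist(raw$intercept_bmi)
  for (nm in c("behaviour_prevalences", "behaviour_effects_bmi",
               "confounder_distributions", "confounder_effects_bmi")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- rapply(raw[[nm]], unlist,
                                                  how = "replace")
  }
  if (!is.null(raw$behaviour_effects_bmi))
    args$behaviour_effects_bmi <- lapply(raw$behaviour_effects_bmi, unlist)
  if (!is.null(raw$confounder_effects_bmi))
    args$confounder_effects_bmi <- unlist(raw$confounder_effects_bmi)
  if (!is.null(raw$interaction_offsets))
    args$interaction_offsets <- unlist(raw$interaction_offsets)
  do.call(synthetic_config, args)
}

#' Inject a stratum-specific interaction offset
#'
#' Returns a copy of the configuration whose `interaction_offsets` includes
#' the given entry (added to any existing offset for that stratum); all other
#' fields are unchanged.
#'
#' @param config A [synthetic_config()].
#' @param stratum A valid 5-digit stratum key.
#' @param offset_bmi BMI offset in kg/m^2.
#' @return The modified `synthetic_config`.
#' @export
inject_stratum_interaction <- function(config, stratum, offset_bmi) {
  validate_stratum_key(stratum)
  off <- config$interaction_offsets
  off[stratum] <- (if (stratum %in% names(off)) off[[stratum]] else 0) +
    offset_bmi
  config$interaction_offsets <- off
  config
}

# Additive fixed-part stratum effect (excluding intercept) for each of the 48
# keys, given a per-sex effect vector.
stratum_additive_effects <- function(effects) {
  keys <- enumerate_strata()
  vapply(keys, function(k) {
    d <- as.integer(strsplit(k, "")[[1]])
    d[1] * effects[["sleep"]] + d[2] * effects[["fv"]] +
      d[3] * effects[["alcohol"]] + d[4] * effects[["pa"]] +
      (d[5] == 1L) * effects[["smoking_current"]] +
      (d[5] == 2L) * effects[["smoking_never"]]
  }, numeric(1))
}

# Population probability of each stratum under independent behaviour draws.
stratum_probabilities <- function(prev) {
  keys <- enumerate_strata()
  psmk <- prev$smoking[c("previous", "current", "never")]
  vapply(keys, function(k) {
    d <- as.integer(strsplit(k, "")[[1]])
    pb <- function(p, x) if (x == 1L) p else 1 - p
    pb(prev$sleep, d[1]) * pb(prev$fv, d[2]) * pb(prev$alcohol, d[3]) *
      pb(prev$pa, d[4]) * psmk[[d[5] + 1L]]
  }, numeric(1))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draw order per sex (one seeded stream): behaviour codes (sleep, fruit&veg,
#' alcohol, physical activity, smoking), latent stratum offsets, confounders
#' (age, TDI, ethnicity, employment), BMI residual noise, raw questionnaire
#' measures, then (under `independent-logit`) the binary outcome.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_cohort` with elements `records`
#'   (raw-scale `data.frame`, one row per person) and `truth`
#'   (class `true_parameters`): per-sex fixed effects, realised per-stratum
#'   latent offsets, residual SD, the implied between-stratum variance of the
#'   stratum means, and the drawn behaviour codes.
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  with_seed(config$seed, {
    keys <- enumerate_strata()
    recs <- list(); codes <- list(); truth_sex <- list()
    for (s in c("male", "female")) {
      n <- config$n_per_sex
      prev <- config$behaviour_prevalences[[s]]
      eff <- config$behaviour_effects_bmi[[s]]
      cd <- config$confounder_distributions[[s]]
      ce <- config$confounder_effects_bmi

      sleep_c <- rbinom(n, 1, prev$sleep)
      fv_c <- rbinom(n, 1, prev$fv)
      alc_c <- rbinom(n, 1, prev$alcohol)
      pa_c <- rbinom(n, 1, prev$pa)
      smk <- sample(names(SMOKING_CODES), n, replace = TRUE,
                    prob = prev$smoking[c("previous", "current", "never")])
      smk_c <- unname(SMOKING_CODES[smk])
      key <- sprintf("%d%d%d%d%d", sleep_c, fv_c, alc_c, pa_c, smk_c)

      u_extra <- rnorm(48, 0, config$extra_stratum_sd)
      names(u_extra) <- keys
      u_inter <- setNames(numeric(48), keys)
      if (length(config$interaction_offsets))
        u_inter[names(config$interaction_offsets)] <-
          config$interaction_offsets
      u_all <- u_extra + u_inter

      age <- rnorm(n, cd$age[["mean"]], cd$age[["sd"]])
      tdi <- rnorm(n, cd$tdi[["mean"]], cd$tdi[["sd"]])
      white <- rbinom(n, 1, cd$white)
      employed <- rbinom(n, 1, cd$employed)

      add_eff <- stratum_additive_effects(eff)
      fixed <- config$intercept_bmi[[s]] + add_eff[key] +
        ce[["age"]] * (age - cd$age[["mean"]]) +
        ce[["tdi"]] * (tdi - cd$tdi[["mean"]]) +
        ce[["nonwhite"]] * (1 - white) + ce[["notemployed"]] * (1 - employed)
      bmi <- fixed + u_all[key] + rnorm(n, 0, config$residual_sd_bmi)

      raw <- draw_raw_measures(sleep_c, fv_c, alc_c, pa_c)

      rec <- data.frame(
        sex = s,
        sleep_hours = raw$sleep_hours, fv_portions = raw$fv_portions,
        alcohol_units = raw$alcohol_units,
        pa_moderate_min = raw$pa_moderate_min,
        pa_vigorous_min = raw$pa_vigorous_min,
        smoking = smk, age = age, tdi = tdi,
        ethnicity = ifelse(white == 1, "white", "non-white"),
        employment = ifelse(employed == 1, "employed",
                            "not-employed-or-retired"),
        bmi = bmi, stringsAsFactors = FALSE)

      if (config$obesity_rule == "independent-logit") {
        u_logit <- rnorm(48, 0, config$logit_sigma_u)
        names(u_logit) <- keys
        p <- plogis(config$logit_intercept + u_logit[key])
        rec$obese <- rbinom(n, 1, p)
      } else {
        u_logit <- NULL
        rec$obese <- as.integer(bmi >= 30)
      }

      recs[[s]] <- rec
      codes[[s]] <- data.frame(
        sex = s, sleep_meets = sleep_c, fv_meets = fv_c,
        alcohol_meets = alc_c, pa_meets = pa_c, smoking_code = smk_c,
        stratum = key, stringsAsFactors = FALSE)
      pstrat <- stratum_probabilities(prev)
      mu <- add_eff + u_all  # stratum deviation from intercept
      mbar <- sum(pstrat * mu)
      truth_sex[[s]] <- list(
        intercept = config$intercept_bmi[[s]],
        behaviour_effects = eff,
        stratum_additive = add_eff,
        stratum_offsets = u_all,
        stratum_means = config$intercept_bmi[[s]] + mu,
        logit_offsets = u_logit,
        implied_between_variance = sum(pstrat * (mu - mbar)^2))
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    records <- cbind(id = seq_len(nrow(records)), records)
    codes <- do.call(rbind, codes)
    rownames(codes) <- NULL
    truth <- structure(
      list(per_sex = truth_sex, residual_sd = config$residual_sd_bmi,
           codes = codes, config = config),
      class = "true_parameters")
    structure(list(records = records, truth = truth),
              class = "synthetic_cohort")
  })
}

# Raw questionnaire-scale measures consistent with the drawn codes; drawn
# uniformly within the code-consistent range so guideline recoding is exact.
draw_raw_measures <- function(sleep_c, fv_c, alc_c, pa_c) {
  n <- length(sleep_c)
  sleep_hours <- ifelse(sleep_c == 1, runif(n, 7, 9),
                        ifelse(runif(n) < 0.5, runif(n, 4, 6.9),
                               runif(n, 9.1, 12)))
  fv_portions <- ifelse(fv_c == 1, sample(5:10, n, replace = TRUE),
                        sample(0:4, n, replace = TRUE))
  alcohol_units <- ifelse(alc_c == 1, runif(n, 0, 14), runif(n, 14.5, 60))
  # For guideline-meeting activity, the 150-min moderate route and the
  # 75-min vigorous route are both represented.
  route <- runif(n)
  pa_moderate <- ifelse(pa_c == 1,
                        ifelse(route < 0.5, runif(n, 150, 600),
                               runif(n, 0, 149)),
                        runif(n, 0, 149))
  pa_vigorous <- ifelse(pa_c == 1,
                        ifelse(route < 0.5, runif(n, 0, 74),
                               runif(n, 75, 300)),
                        runif(n, 0, 74))
  list(sleep_hours = sleep_hours, fv_portions = fv_portions,
       alcohol_units = alcohol_units, pa_moderate_min = pa_moderate,
       pa_vigorous_min = pa_vigorous)
}

#' Emit the raw questionnaire table
#'
#' Returns (and optionally writes as CSV) the raw-scale person-level table
#' with columns `id`, `sex`, `sleep_hours`, `fv_portions`, `alcohol_units`,
#' `pa_moderate_min`, `pa_vigorous_min`, `smoking`, `age`, `tdi`,
#' `ethnicity`, `employment`, `bmi` (plus `obese` under the
#' `independent-logit` rule).
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()] (or its
#'   `records` data.frame).
#' @param path Optional CSV path; stratum-free raw table written with a
#'   header row.
#' @return The raw `data.frame`, invisibly if written to `path`.
#' @export
emit_raw_questionnaire <- function(cohort, path = NULL) {
  records <- if (inherits(cohort, "synthetic_cohort")) cohort$records
             else as.data.frame(cohort)
  if (!is.null(records$obese) &&
      (!inherits(cohort, "synthetic_cohort") ||
       cohort$truth$config$obesity_rule == "threshold-on-BMI")) {
    records$obese <- NULL  # derivable from BMI; keep the questionnaire raw
  }
  if (!is.null(path)) {
    write.csv(records, path, row.names = FALSE, quote = TRUE)
    return(invisible(records))
  }
  records
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", nrow(x$records), " records (",
      x$truth$config$n_per_sex, " per sex), obesity rule '",
      x$truth$config$obesity_rule, "'\n", sep = "")
  invisible(x)
}

#' @export
print.true_parameters <- function(x, ...) {
  cat("True generating parameters\n")
  for (s in names(x$per_sex)) {
    t <- x$per_sex[[s]]
    cat(sprintf("  %s: intercept %.2f, implied between-stratum variance %.4f\n",
                s, t$intercept, t$implied_between_variance))
  }
  cat(sprintf("  residual SD %.4f kg/m^2\n", x$residual_sd))
  invisible(x)
}
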