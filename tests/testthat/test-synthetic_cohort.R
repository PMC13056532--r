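test_that("generation is deterministic given config and seed", {
  cfg <- synthetic_config(n_per_sex = 500, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$codes, b$truth$codes)
  expect_identical(a$truth$per_sex$male$stratum_offsets,
                   b$truth$per_sex$male$stratum_offsets)
  c <- generate_cohort(synthetic_config(n_per_sex = 500, seed = 8))
  expect_false(identical(a$records$bmi, c$records$bmi))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(synthetic_config(n_per_sex = 0), "n_per_sex")
  expect_error(synthetic_config(residual_sd_bmi = 0), "residual_sd_bmi")
  bp <- default_prev <- maihda:::default_behaviour_prevalences()
  bp$male$fv <- 1.2
  expect_error(synthetic_config(behaviour_prevalences = bp), "fv")
  bp2 <- default_prev
  bp2$female$smoking <- c(previous = 0.5, current = 0.4, never = 0.2)
  expect_error(synthetic_config(behaviour_prevalences = bp2), "sum to 1")
})

test_that("raw measures recode back to the drawn codes exactly", {
  for (seed in c(1, 99)) {
    cohort <- generate_cohort(synthetic_config(n_per_sex = 2000, seed = seed))
    coded <- recode_behaviours(emit_raw_questionnaire(cohort))
    codes <- cohort$truth$codes
    expect_identical(coded$sleep_meets, codes$sleep_meets)
    expect_identical(coded$fv_meets, codes$fv_meets)
    expect_identical(coded$alcohol_meets, codes$alcohol_meets)
    expect_identical(coded$pa_meets, codes$pa_meets)
    expect_identical(coded$smoking_code, codes$smoking_code)
    expect_identical(encode_stratum(coded), codes$stratum)
  }
  # code-consistent ranges on the raw scale
  cohort <- generate_cohort(synthetic_config(n_per_sex = 2000, seed = 3))
  rec <- cohort$records
  codes <- cohort$truth$codes
  expect_true(all(rec$sleep_hours[codes$sleep_meets == 1] >= 7 &
                    rec$sleep_hours[codes$sleep_meets == 1] <= 9))
  expect_true(all(rec$alcohol_units[codes$alcohol_meets == 1] <= 14))
  expect_true(all(rec$alcohol_units[codes$alcohol_meets == 0] > 14))
})

test_that("the CSV round trip preserves the cohort", {
  cohort <- generate_cohort(synthetic_config(n_per_sex = 300, seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  emit_raw_questionnaire(cohort, path)
  back <- read.csv(path, stringsAsFactors = FALSE)
  coded <- recode_behaviours(back)
  expect_identical(coded$sleep_meets, cohort$truth$codes$sleep_meets)
  expect_identical(coded$smoking_code, cohort$truth$codes$smoking_code)
})

test_that("the purely additive model has exact stratum means in the truth", {
  cfg <- synthetic_config(n_per_sex = 100, seed = 5, extra_stratum_sd = 0)
  truth <- generate_cohort(cfg)$truth
  for (s in c("male", "female")) {
    t <- truth$per_sex[[s]]
    eff <- cfg$behaviour_effects_bmi[[s]]
    for (k in c("00000", "11112", "01012")) {
      d <- decode_stratum(k)
      expected <- t$intercept +
        d$sleep_meets * eff[["sleep"]] + d$fv_meets * eff[["fv"]] +
        d$alcohol_meets * eff[["alcohol"]] + d$pa_meets * eff[["pa"]] +
        (d$smoking_code == 1) * eff[["smoking_current"]] +
        (d$smoking_code == 2) * eff[["smoking_never"]]
      expect_equal(unname(t$stratum_means[k]), unname(expected),
                   tolerance = 1e-12)
    }
    expect_true(all(t$stratum_offsets == 0))
  }
})

test_that("sampled behaviour prevalences are calibrated to the configuration", {
  cfg <- synthetic_config(n_per_sex = 100000, seed = 13)
  codes <- generate_cohort(cfg)$truth$codes
  for (s in c("male", "female")) {
    cs <- codes[codes$sex == s, ]
    n <- nrow(cs)
    prev <- cfg$behaviour_prevalences[[s]]
    checks <- list(
      c(mean(cs$sleep_meets), prev$sleep),
      c(mean(cs$fv_meets), prev$fv),
      c(mean(cs$alcohol_meets), prev$alcohol),
      c(mean(cs$pa_meets), prev$pa),
      c(mean(cs$smoking_code == 1L), prev$smoking[["current"]]),
      c(mean(cs$smoking_code == 0L), prev$smoking[["previous"]]),
      c(mean(cs$smoking_code == 2L), prev$smoking[["never"]]))
    for (ch in checks) {
      se <- sqrt(ch[2] * (1 - ch[2]) / n)
      expect_lt(abs(ch[1] - ch[2]), 3 * se)
    }
  }
})

test_that("interaction injection changes only the targeted stratum", {
  cfg <- synthetic_config(n_per_sex = 1000, seed = 17)
  cfg0 <- inject_stratum_interaction(cfg, "11112", 0.0)
  expect_identical(generate_cohort(cfg)$records,
                   generate_cohort(cfg0)$records)
  cfg2 <- inject_stratum_interaction(cfg, "11112", 2.0)
  expect_identical(cfg2$interaction_offsets, c("11112" = 2.0))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg2)
  in_strat <- a$truth$codes$stratum == "11112"
  expect_equal(b$records$bmi[in_strat] - a$records$bmi[in_strat],
               rep(2, sum(in_strat)), tolerance = 1e-12)
  expect_identical(a$records$bmi[!in_strat], b$records$bmi[!in_strat])
  expect_error(inject_stratum_interaction(cfg, "99999", 1), "invalid")
})

test_that("the independent-logit rule draws the outcome on the latent scale", {
  cfg <- synthetic_config(n_per_sex = 50000, seed = 19,
                          obesity_rule = "independent-logit",
                          logit_intercept = 0, logit_sigma_u = 0)
  ch <- generate_cohort(cfg)
  expect_true(all(ch$records$obese %in% 0:1))
  p <- mean(ch$records$obese)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / nrow(ch$records)))
})
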