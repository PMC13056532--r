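test_that("guideline recoding applies the documented thresholds", {
  raw <- data.frame(
    sex = "male",
    sleep_hours = c(8, 7, 9, 6.9, 9.1, NA),
    fv_portions = c(5, 10, 4, 0, 5, NA),
    alcohol_units = c(14, 0, 14.1, 50, 14, NA),
    pa_moderate_min = c(150, 0, 149, 0, NA, 200),
    pa_vigorous_min = c(0, 75, 74, 10, 80, NA),
    smoking = c("current", "previous", "never", "never", "current", NA),
    bmi = 27)
  coded <- recode_behaviours(raw)
  expect_identical(coded$sleep_meets, c(1L, 1L, 1L, 0L, 0L, NA))
  expect_identical(coded$fv_meets, c(1L, 1L, 0L, 0L, 1L, NA))
  expect_identical(coded$alcohol_meets, c(1L, 1L, 0L, 0L, 1L, NA))
  # either route meets activity; a missing component only matters when the
  # other one is below threshold
  expect_identical(coded$pa_meets, c(1L, 1L, 0L, 0L, 1L, 1L))
  expect_identical(coded$smoking_code, c(1L, 0L, 2L, 2L, 1L, NA))
})

test_that("weight-status categories partition the BMI axis", {
  expect_identical(classify_weight_status(24.9), "normal")
  expect_identical(classify_weight_status(30.0), "obese")
  expect_identical(classify_weight_status(18.5), "normal")
  expect_identical(classify_weight_status(29.95), "overweight")
  # brute-force grid: total, mutually exclusive, exhaustive
  grid <- seq(0.1, 80, by = 0.1)
  ws <- classify_weight_status(grid)
  expect_false(anyNA(ws))
  expect_setequal(unique(ws), c("underweight", "normal", "overweight", "obese"))
  expect_identical(ws[grid < 18.5], rep("underweight", sum(grid < 18.5)))
  expect_error(classify_weight_status(-1), "positive")
  expect_error(classify_weight_status(Inf), "finite")
})

test_that("the exclusion cascade applies reasons in order and conserves records", {
  fx <- rbind(
    coded_record(alcohol = NA),                        # missing lifestyle
    coded_record(tdi = NA),                            # missing confounder
    coded_record(bmi = NA),                            # missing BMI
    coded_record(bmi = 17.0),                          # underweight
    coded_record(bmi = 24.0))                          # retained
  out <- apply_exclusions(fx, "bmi-linear")
  expect_identical(out$ledger$retained, 1L)
  expect_identical(unname(out$ledger$reasons),
                   c(1L, 1L, 1L, 1L, 0L))
  # first-applicable-reason rule: a record missing both lifestyle and BMI
  # counts under lifestyle only
  both <- coded_record(alcohol = NA, bmi = NA)
  out2 <- apply_exclusions(rbind(fx, both), "bmi-linear")
  expect_identical(unname(out2$ledger$reasons["missing_lifestyle"]), 2L)
  expect_identical(unname(out2$ledger$reasons["missing_bmi"]), 1L)

  # binary contrasts drop the out-of-contrast category
  fx2 <- rbind(coded_record(bmi = 24), coded_record(bmi = 27),
               coded_record(bmi = 32))
  ob <- apply_exclusions(fx2, "obesity-vs-normal")
  expect_identical(ob$ledger$retained, 2L)
  expect_identical(unname(ob$ledger$reasons["contrast"]), 1L)
  ov <- apply_exclusions(fx2, "overweight-vs-normal")
  expect_identical(sort(ov$data$weight_status), c("normal", "overweight"))

  expect_error(apply_exclusions(fx[0, ], "bmi-linear"), "empty")
})

test_that("ledger counts are invariant to record order and conserve totals", {
  cohort <- generate_cohort(synthetic_config(n_per_sex = 3000, seed = 31))
  coded <- recode_behaviours(emit_raw_questionnaire(cohort))
  # inject missingness deterministically
  coded$alcohol_meets[seq(1, nrow(coded), by = 17)] <- NA
  coded$tdi[seq(2, nrow(coded), by = 23)] <- NA
  coded$bmi[seq(3, nrow(coded), by = 31)] <- NA
  coded$weight_status[is.na(coded$bmi)] <- NA
  out <- apply_exclusions(coded, "obesity-vs-normal")
  expect_identical(out$ledger$input,
                   out$ledger$retained + sum(out$ledger$reasons))
  perm <- sample(nrow(coded))
  out2 <- apply_exclusions(coded[perm, ], "obesity-vs-normal")
  expect_identical(out$ledger$reasons, out2$ledger$reasons)
})

test_that("descriptive table matches an independent pass over the records", {
  cohort <- generate_cohort(synthetic_config(n_per_sex = 4000, seed = 32))
  coded <- recode_behaviours(emit_raw_questionnaire(cohort))
  tab <- descriptive_table(coded)

  males <- coded[coded$sex == "male", ]
  cur <- sum(males$smoking_code == 1L)
  row <- tab[tab$sex == "male" & tab$variable == "smoking" &
               tab$level == "current", ]
  expect_identical(row$n, cur)
  expect_equal(row$percent, round(100 * cur / nrow(males), 1))
  age_row <- tab[tab$sex == "female" & tab$variable == "age", ]
  expect_equal(age_row$mean, mean(coded$age[coded$sex == "female"]))
  bmi_row <- tab[tab$sex == "male" & tab$variable == "bmi", ]
  expect_equal(bmi_row$median, median(males$bmi))

  # percentages within each categorical variable sum to 100 +/- 0.1
  for (s in c("male", "female")) {
    for (v in unique(tab$variable[!is.na(tab$percent)])) {
      p <- tab$percent[tab$sex == s & tab$variable == v]
      expect_lt(abs(sum(p) - 100), 0.1 + 1e-9)
    }
  }
})

test_that("VIFs match the closed form and flag exact collinearity", {
  set.seed(41)
  n <- 500
  # orthogonal by construction
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, 1), each = n / 2)
  d0 <- collinearity_diagnostics(cbind(a = x1, b = x2))
  expect_equal(unname(d0$vif), c(1, 1), tolerance = 1e-12)

  # two correlated predictors: VIF = 1 / (1 - r^2)
  z <- rnorm(n)
  x3 <- z + rnorm(n)
  x4 <- z + rnorm(n)
  r <- cor(x3, x4)
  d1 <- collinearity_diagnostics(cbind(a = x3, b = x4))
  expect_equal(unname(d1$vif), rep(1 / (1 - r^2), 2), tolerance = 1e-10)

  d2 <- collinearity_diagnostics(cbind(a = x3, b = x4, c = x3))
  expect_true(all(c("a", "c") %in% d2$flagged))
  expect_identical(d2$max_vif, Inf)
})
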