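test_that("VPC follows the variance-partition formula on both scales", {
  expect_identical(compute_vpc(0, 15.15), 0)
  expect_equal(compute_vpc(0.70, 15.15), 100 * 0.70 / 15.85,
               tolerance = 1e-12)
  expect_equal(round(compute_vpc(0.70, 15.15), 2), 4.42)
  # latent-scale logistic denominator: equal components give exactly 50%
  expect_identical(compute_vpc(logistic_latent_variance(),
                               family = "logistic"), 50)
  expect_equal(round(logistic_latent_variance(), 2), 3.29)
  expect_error(compute_vpc(-0.1, 1), "non-negative")
  expect_error(compute_vpc(0.5, 0), "positive")
})

test_that("PCV reports the positive reduction and flags increases", {
  expect_identical(compute_pcv(0.7, 0.7), 0)
  expect_identical(compute_pcv(0.7, 0), 100)
  expect_equal(round(compute_pcv(0.70, 0.05), 1), 92.9)
  neg <- compute_pcv(0.5, 0.6)
  expect_lt(as.numeric(neg), 0)
  expect_true(isTRUE(attr(neg, "increased")))
  expect_error(compute_pcv(0, 0.1), "positive")
})

test_that("VPC and PCV are invariant to rescaling the outcome", {
  set.seed(301)
  g <- sample(letters[1:12], 1500, replace = TRUE)
  y <- rnorm(1500) + rnorm(12, 0, 0.8)[as.integer(factor(g))]
  f1 <- fit_linear(y, intercept_design(1500), g)
  f2 <- fit_linear(3.7 * y, intercept_design(1500), g)
  expect_equal(compute_vpc(f1$sigma2_u, f1$sigma2_e),
               compute_vpc(f2$sigma2_u, f2$sigma2_e), tolerance = 1e-10)
  expect_equal(as.numeric(compute_pcv(f1$sigma2_u, f1$sigma2_u / 2)),
               as.numeric(compute_pcv(f2$sigma2_u, f2$sigma2_u / 2)),
               tolerance = 1e-10)
})

test_that("stratum predictions on the toy fit are the grand mean plus BLUPs", {
  y <- c(1, 3, 5, 7)
  X <- intercept_design(4)
  f <- c("A", "A", "B", "B")
  fit <- fit_linear(y, X, f)
  pr <- predict_strata(fit, y, X, f, linear_blups(fit))
  expect_equal(pr$excl_est, rep(4, 2), tolerance = 1e-6)
  expect_equal(pr$incl_est, c(2.25, 5.75), tolerance = 1e-6)
  expect_equal(pr$observed, c(2, 6), tolerance = 1e-12)
  # the linear-scale identity: including minus excluding equals u_hat
  expect_equal(pr$incl_est - pr$excl_est, pr$u_hat, tolerance = 1e-12)
  # intervals contain their point estimates
  expect_true(all(pr$incl_lower <= pr$incl_est & pr$incl_est <= pr$incl_upper))
  expect_true(all(pr$excl_lower <= pr$excl_est & pr$excl_est <= pr$excl_upper))
})

test_that("logistic predictions stay in [0,1] and move with the intercept sign", {
  set.seed(302)
  keys <- enumerate_strata()
  n <- 10000
  f <- factor(sample(keys, n, replace = TRUE), levels = keys)
  u <- rnorm(48, 0, 0.6); names(u) <- keys
  y <- rbinom(n, 1, plogis(-0.2 + u[as.character(f)]))
  X <- intercept_design(n)
  fit <- fit_logistic(y, X, f)
  eb <- logistic_eb_intercepts(fit)
  pr <- predict_strata(fit, y, X, f, eb)
  ok <- !is.na(pr$incl_est)
  expect_true(all(pr$incl_est[ok] >= 0 & pr$incl_est[ok] <= 1))
  expect_true(all(pr$incl_lower[ok] >= 0 & pr$incl_upper[ok] <= 1))
  # including-RE probability lies on the u_hat side of the excluding-RE one
  side <- sign(pr$incl_est[ok] - pr$excl_est[ok])
  expect_true(all(side == sign(pr$u_hat[ok]) | pr$u_hat[ok] == 0))
  expect_true(all(pr$incl_lower[ok] <= pr$incl_est[ok] &
                    pr$incl_est[ok] <= pr$incl_upper[ok]))
})

test_that("empty strata fall back to the fixed part at decoded codes", {
  set.seed(303)
  # only never-smokers present: 32 strata empty
  keys <- enumerate_strata()
  present <- keys[substr(keys, 5, 5) == "2"]
  n <- 3000
  f <- factor(sample(present, n, replace = TRUE), levels = keys)
  y <- rnorm(n, 27, 3)
  X <- intercept_design(n)
  fit <- fit_linear(y, X, f)
  bl <- linear_blups(fit)
  ed <- maihda:::empty_stratum_design(1, "intercept")
  pr <- predict_strata(fit, y, X, f, bl, empty_design = ed)
  empty <- pr$empty
  expect_identical(sum(empty), 32L)
  expect_equal(pr$excl_est[empty], rep(unname(fit$beta), 32),
               tolerance = 1e-9)
  expect_true(all(pr$u_hat[empty] == 0))
})

test_that("interaction flags require strictly disjoint unrounded intervals", {
  base <- data.frame(stratum = c("a", "b", "c", "d"),
                     incl_est = c(27.2, 27.2, 27.8, 27.2),
                     incl_lower = c(26.93, 26.9, 27.5049, 27.0),
                     incl_upper = c(27.4951, 27.5, 28.04, 27.4),
                     excl_est = c(27.2, 27.2, 27.75, 27.2),
                     excl_lower = c(26.93, 26.9, 26.93, 26.5),
                     excl_upper = c(27.4951, 27.5, 27.4951, 28.0),
                     stringsAsFactors = FALSE)
  fl <- flag_interactions(base)
  expect_false(fl$interaction_flag[1])  # identical intervals
  expect_false(fl$interaction_flag[2])  # shared endpoint: not disjoint
  # unrounded values that print as the touching pair (26.9-27.5 vs 27.5-28.0)
  expect_true(fl$interaction_flag[3])
  expect_identical(round(fl$excl_lower[3], 1), 26.9)
  expect_identical(round(fl$excl_upper[3], 1), 27.5)
  expect_identical(round(fl$incl_lower[3], 1), 27.5)
  expect_identical(round(fl$incl_upper[3], 1), 28.0)
  expect_false(fl$interaction_flag[4])  # nested
  bad <- base
  bad$incl_lower[1] <- 99
  expect_error(flag_interactions(bad), "malformed")
})

test_that("ranking is deterministic with key tie-breaks and bounded k", {
  pr <- data.frame(stratum = c("00002", "00001", "00000", "11112"),
                   incl_est = c(27, 27, 26, 30),
                   stringsAsFactors = FALSE)
  rk <- rank_strata(pr, k = 2)
  expect_identical(rk$ranked$stratum, c("00000", "00001", "00002", "11112"))
  perm <- rank_strata(pr[c(3, 1, 4, 2), ], k = 2)
  expect_identical(rk$ranked$stratum, perm$ranked$stratum)
  expect_identical(rk$lowest$stratum, c("00000", "00001"))
  expect_identical(rk$highest$stratum, c("00002", "11112"))
  full <- rank_strata(pr, k = 4)
  expect_identical(full$lowest, full$ranked)
  expect_warning(rank_strata(pr, k = 10), "truncated")
})

test_that("lowest-BMI strata meet the activity and sleep guidelines", {
  hits <- vapply(1:10, function(i) {
    set <- male_analysis_set(generate_cohort(
      synthetic_config(n_per_sex = 20000, seed = 400 + i)))
    d <- maihda:::build_design(set$data, 2)
    fit <- fit_linear(set$data$bmi, d$X, set$f)
    pr <- predict_strata(fit, set$data$bmi, d$X, set$f, linear_blups(fit))
    low <- rank_strata(pr, k = 5)$lowest$stratum
    all(substr(low, 4, 4) == "1") && all(substr(low, 1, 1) == "1")
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
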