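# MAIHDA metrics: variance decomposition (VPC, PCV), per-stratum predictions
# including/excluding the random intercept, interaction flags via strict
# confidence-interval non-overlap, and ranked strata tables.

#' Latent-scale level-1 variance of the logistic model
#'
#' The variance of the standard logistic distribution, pi^2 / 3, used as the
#' within-stratum variance in the logistic VPC (the individual-level variance
#' is not estimated on the probability scale).
#'
#' @return `pi^2 / 3` (about 3.2899, conventionally printed 3.29).
#' @export
logistic_latent_variance <- function() pi^2 / 3

#' Variance partition coefficient (percent)
#'
#' `VPC = 100 * sigma2_u / (sigma2_u + sigma2_within)`. For logistic models
#' the within component is fixed at the latent-scale constant `pi^2 / 3`.
#'
#' @param sigma2_u Between-stratum variance (level 2), >= 0.
#' @param sigma2_e Within-stratum variance (level 1); ignored when
#'   `family = "logistic"`.
#' @param family `"linear"` or `"logistic"`.
#' @return VPC in percent, in `[0, 100]`.
#' @export
#' @examples
#' compute_vpc(0.70, 15.15)                       # 4.42 (2 dp)
#' compute_vpc(logistic_latent_variance(), family = "logistic")  # 50
compute_vpc <- function(sigma2_u, sigma2_e = NULL,
                        family = c("linear", "logistic")) {
  family <- match.arg(family)
  if (!is.finite(sigma2_u) || sigma2_u < 0)
    stop_maihda("sigma2_u must be non-negative")
  within <- if (family == "logistic") logistic_latent_variance() else sigma2_e
  if (is.null(within) || !is.finite(within) || within <= 0)
    stop_maihda("within-stratum variance must be positive")
  100 * sigma2_u / (sigma2_u + within)
}

#' Proportional change in variance (percent)
#'
#' The percentage of the null model's between-stratum variance explained
#' when fixed effects are added:
#' `PCV = 100 * (sigma2_null - sigma2_model) / sigma2_null`. Reported with
#' the positive-reduction sign convention; a negative value (variance
#' increased) is allowed and carries the attribute `increased = TRUE`.
#'
#' @param sigma2_u_null Between-stratum variance of the null model (> 0).
#' @param sigma2_u_model Between-stratum variance of the richer model (>= 0).
#' @return PCV in percent (<= 100).
#' @export
#' @examples
#' compute_pcv(0.70, 0.05)  # 92.9 (1 dp)
compute_pcv <- function(sigma2_u_null, sigma2_u_model) {
  if (!is.finite(sigma2_u_null) || sigma2_u_null <= 0)
    stop_maihda("null-model between-stratum variance must be positive")
  if (!is.finite(sigma2_u_model) || sigma2_u_model < 0)
    stop_maihda("model between-stratum variance must be non-negative")
  pcv <- 100 * (sigma2_u_null - sigma2_u_model) / sigma2_u_null
  if (pcv < 0) attr(pcv, "increased") <- TRUE
  pcv
}

#' Per-stratum predictions including and excluding the random intercept
#'
#' For every stratum (all 48 keys, including empty ones): the prediction
#' excluding the random effect is the stratum average of fixed-part
#' predictions over member rows (probability scale via the inverse link per
#' member for logistic fits); the prediction including the random effect adds
#' the empirical-Bayes intercept on the linear-predictor scale before the
#' link. Intervals are Wald on the (averaged) linear predictor using the
#' fixed-effect covariance; the including-RE interval adds the posterior
#' variance of the intercept (fixed-random covariance ignored, a documented
#' approximation). Logistic intervals are built on the logit scale and
#' inverse-linked, guaranteeing probabilities in `[0, 1]`.
#'
#' @param fit A [fit_linear()] or [fit_logistic()] result.
#' @param y Outcome vector of the analysis set (for observed stratum means).
#' @param X Design matrix of the analysis set.
#' @param strata Stratum identifier per record (same levels as the fit).
#' @param intercepts Output of [linear_blups()] or
#'   [logistic_eb_intercepts()] from the same fit.
#' @param empty_design Optional matrix (rows named by stratum key) of design
#'   rows used for empty strata (behaviour codes decoded from the key,
#'   confounders at their centring values); empty strata get `NA` otherwise.
#' @param level Confidence level.
#' @return A `data.frame` of class `stratum_predictions`: `stratum`, `n`,
#'   `observed`, `incl_est`, `incl_lower`, `incl_upper`, `excl_est`,
#'   `excl_lower`, `excl_upper`, `u_hat`, `u_lower`, `u_upper`, `empty`.
#' @export
predict_strata <- function(fit, y, X, strata, intercepts,
                           empty_design = NULL, level = 0.95) {
  logistic <- inherits(fit, "maihda_glmm")
  if (!logistic && !inherits(fit, "maihda_lmm"))
    stop_maihda("fit must come from fit_linear() or fit_logistic()")
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop_maihda("model/data mismatch: y vs X")
  f <- if (is.factor(strata)) strata else factor(strata)
  lev <- levels(f)
  if (!identical(sort(intercepts$stratum), sort(lev)))
    stop_maihda("model/data mismatch: intercepts do not cover the strata")
  z <- stats::qnorm(1 - (1 - level) / 2)
  ub <- setNames(intercepts$u_hat, intercepts$stratum)
  uv <- setNames(intercepts$post_sd^2, intercepts$stratum)

  eta <- as.numeric(X %*% fit$beta)
  n_j <- as.integer(table(f))
  names(n_j) <- lev

  # per-stratum mean design row and mean linear predictor
  xbar <- matrix(NA_real_, length(lev), ncol(X),
                 dimnames = list(lev, colnames(X)))
  pres <- lev[n_j > 0]
  xs <- rowsum(X, f)
  xbar[rownames(xs), ] <- xs / n_j[rownames(xs)]
  abar <- setNames(rep(NA_real_, length(lev)), lev)
  abar[pres] <- (rowsum(eta, f) / n_j[pres])[, 1]

  obs <- setNames(rep(NA_real_, length(lev)), lev)
  obs[pres] <- (rowsum(as.numeric(y), f) / n_j[pres])[, 1]

  # mean per-member inverse-link prediction (logistic); linear: same as abar
  if (logistic) {
    pbar_ex <- setNames(rep(NA_real_, length(lev)), lev)
    pbar_ex[pres] <- (rowsum(plogis(eta), f) / n_j[pres])[, 1]
    pbar_in <- setNames(rep(NA_real_, length(lev)), lev)
    pbar_in[pres] <- (rowsum(plogis(eta + ub[as.character(f)]), f) /
                        n_j[pres])[, 1]
  }

  empty <- n_j == 0L
  if (any(empty) && !is.null(empty_design)) {
    ek <- intersect(lev[empty], rownames(empty_design))
    xbar[ek, ] <- empty_design[ek, colnames(X), drop = FALSE]
    abar[ek] <- as.numeric(xbar[ek, , drop = FALSE] %*% fit$beta)
    if (logistic) {
      pbar_ex[ek] <- plogis(abar[ek])
      pbar_in[ek] <- plogis(abar[ek] + ub[ek])
    }
  }

  se_fix <- rep(NA_real_, length(lev))
  has_x <- !is.na(xbar[, 1])
  if (any(has_x)) {
    Xb <- xbar[has_x, , drop = FALSE]
    se_fix[has_x] <- sqrt(pmax(rowSums((Xb %*% fit$vcov_beta) * Xb), 0))
  }
  se_in <- sqrt(se_fix^2 + uv[lev])

  if (logistic) {
    ex_est <- unname(pbar_ex[lev]); in_est <- unname(pbar_in[lev])
    lex <- qlogis(pmin(pmax(ex_est, 1e-12), 1 - 1e-12))
    lin <- qlogis(pmin(pmax(in_est, 1e-12), 1 - 1e-12))
    out <- data.frame(
      stratum = lev, n = unname(n_j), observed = unname(obs[lev]),
      incl_est = in_est,
      incl_lower = plogis(lin - z * se_in), incl_upper = plogis(lin + z * se_in),
      excl_est = ex_est,
      excl_lower = plogis(lex - z * se_fix),
      excl_upper = plogis(lex + z * se_fix),
      stringsAsFactors = FALSE)
  } else {
    ex_est <- unname(abar[lev]); in_est <- unname(abar[lev] + ub[lev])
    out <- data.frame(
      stratum = lev, n = unname(n_j), observed = unname(obs[lev]),
      incl_est = in_est,
      incl_lower = in_est - z * se_in, incl_upper = in_est + z * se_in,
      excl_est = ex_est,
      excl_lower = ex_est - z * se_fix, excl_upper = ex_est + z * se_fix,
      stringsAsFactors = FALSE)
  }
  out$u_hat <- unname(ub[lev])
  out$u_lower <- intercepts$lower[match(lev, intercepts$stratum)]
  out$u_upper <- intercepts$upper[match(lev, intercepts$stratum)]
  out$empty <- unname(empty)
  class(out) <- c("stratum_predictions", "data.frame")
  out
}

#' Flag multiplicative (interaction) effects by interval non-overlap
#'
#' A stratum is flagged when its intervals for the prediction including vs
#' excluding the random intercept are strictly disjoint, compared on
#' unrounded values (two intervals that share an endpoint after rounding can
#' still be disjoint unrounded).
#'
#' @param predictions A [predict_strata()] result.
#' @return The predictions with a logical `interaction_flag` column.
#' @export
flag_interactions <- function(predictions) {
  p <- predictions
  chk <- function(lo, hi) {
    bad <- !is.na(lo) & !is.na(hi) & lo > hi
    if (any(bad)) stop_maihda("malformed interval: lower > upper")
  }
  chk(p$incl_lower, p$incl_upper)
  chk(p$excl_lower, p$excl_upper)
  p$interaction_flag <- !is.na(p$incl_lower) & !is.na(p$excl_lower) &
    (p$incl_lower > p$excl_upper | p$incl_upper < p$excl_lower)
  p
}

#' Rank strata by predicted outcome
#'
#' Ascending by the prediction including the random intercept, ties broken by
#' stratum key (lexicographic). Returns the full ranked table plus the `k`
#' lowest and `k` highest strata.
#'
#' @param predictions A [predict_strata()] (or [flag_interactions()]) result.
#' @param k Number of strata in each slice (default 5).
#' @param na_drop Drop strata with missing predictions (empty strata without
#'   an `empty_design`) before ranking.
#' @return A list with `ranked` (full table with a `rank` column), `lowest`
#'   and `highest`.
#' @export
rank_strata <- function(predictions, k = 5, na_drop = TRUE) {
  p <- predictions
  if (!nrow(p)) stop_maihda("no predictions to rank")
  if (na_drop) p <- p[!is.na(p$incl_est), , drop = FALSE]
  ord <- order(p$incl_est, p$stratum)
  p <- p[ord, , drop = FALSE]
  p$rank <- seq_len(nrow(p))
  rownames(p) <- NULL
  if (k > nrow(p)) {
    warning("k = ", k, " exceeds the number of strata (", nrow(p),
            "); truncated")
    k <- nrow(p)
  }
  list(ranked = p, lowest = head(p, k), highest = tail(p, k))
}
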