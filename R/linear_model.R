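# Two-level random-intercept linear model, estimated by REML (default) or ML
# through a one-dimensional profiled likelihood over the variance ratio
# psi = sigma2_u / sigma2_e on the log scale.
#
# With a single grouping factor, V = sigma2_e (I + psi * Z Z') is block
# diagonal, so GLS and the profiled criterion reduce to per-stratum
# sufficient statistics (n_j, group means) and a p x p solve — O(n p) per
# criterion evaluation regardless of the number of strata.

# Per-stratum sufficient statistics for the profiled criterion.
lmm_suffstats <- function(y, X, strata) {
  f <- if (is.factor(strata)) strata else factor(strata)
  n_j <- as.integer(table(f))
  present <- n_j > 0L
  # rowsum drops empty levels; expand back to the full level set
  Xs_part <- rowsum(X, f)
  ys_part <- rowsum(y, f)[, 1]
  Xs <- matrix(0, nlevels(f), ncol(X),
               dimnames = list(levels(f), colnames(X)))
  Xs[rownames(Xs_part), ] <- Xs_part
  ys <- setNames(numeric(nlevels(f)), levels(f))
  ys[names(ys_part)] <- ys_part
  list(f = f, levels = levels(f), n_j = n_j, present = present,
       Xsum = Xs, ysum = ys,
       XtX = crossprod(X), Xty = crossprod(X, y)[, 1], yty = sum(y * y),
       n = length(y), p = ncol(X))
}

# GLS fit at a given psi from sufficient statistics. Returns beta, the
# generalised residual sum of squares Q = r' (V/sigma2_e)^{-1} r, and log|A|
# with A = X' (V/sigma2_e)^{-1} X.
lmm_gls <- function(ss, psi) {
  keep <- ss$present
  n_j <- ss$n_j[keep]
  c_j <- psi / (1 + n_j * psi)
  Xs <- ss$Xsum[keep, , drop = FALSE]
  ys <- ss$ysum[keep]
  A <- ss$XtX - crossprod(Xs * sqrt(c_j))
  b <- ss$Xty - colSums(Xs * (c_j * ys))
  R <- chol(A)
  beta <- backsolve(R, forwardsolve(t(R), b))
  q <- ss$yty - 2 * sum(beta * ss$Xty) + sum(beta * (ss$XtX %*% beta)) -
    sum(c_j * (ys - Xs %*% beta)^2)
  list(beta = beta, Q = max(q, 0), logdetA = 2 * sum(log(diag(R))),
       A = A, n_j = n_j)
}

# -2 * profiled log-likelihood up to an additive constant.
lmm_criterion <- function(ss, psi, reml) {
  g <- lmm_gls(ss, psi)
  n_j <- ss$n_j[ss$present]
  df <- if (reml) ss$n - ss$p else ss$n
  crit <- df * log(max(g$Q, .Machine$double.xmin)) + sum(log1p(n_j * psi))
  if (reml) crit <- crit + g$logdetA
  crit
}

# Analytic derivative of the profiled criterion with respect to psi. Because
# beta is the GLS minimiser, only the explicit psi-dependence contributes.
lmm_criterion_deriv <- function(ss, psi, reml) {
  g <- lmm_gls(ss, psi)
  keep <- ss$present
  n_j <- ss$n_j[keep]
  dc <- 1 / (1 + n_j * psi)^2
  Xs <- ss$Xsum[keep, , drop = FALSE]
  r <- as.numeric(ss$ysum[keep] - Xs %*% g$beta)
  df <- if (reml) ss$n - ss$p else ss$n
  d <- -df * sum(dc * r^2) / g$Q + sum(n_j / (1 + n_j * psi))
  if (reml) {
    Ainv <- chol2inv(chol(g$A))
    d <- d - sum(dc * rowSums((Xs %*% Ainv) * Xs))
  }
  d
}

#' Fit a two-level random-intercept linear model
#'
#' Individuals (level 1) nested within strata (level 2):
#' `y_ij = x_ij' beta + u_j + e_ij`, `u_j ~ N(0, sigma2_u)`,
#' `e_ij ~ N(0, sigma2_e)`. Estimated by REML (default) or ML via a profiled
#' likelihood over `psi = sigma2_u / sigma2_e` on the log scale; the boundary
#' estimate `sigma2_u = 0` is allowed and flagged.
#'
#' @param y Numeric outcome vector (e.g. BMI in kg/m^2).
#' @param X Design matrix including an intercept column.
#' @param strata Stratum identifier per record (factor or character); empty
#'   factor levels are retained for prediction.
#' @param method `"REML"` (default) or `"ML"`.
#' @param fix_sigma2_u Optionally fix the level-2 variance (e.g. `0` gives
#'   ordinary least squares) instead of estimating it.
#' @return An object of class `maihda_lmm` with elements `beta`, `vcov_beta`,
#'   `sigma2_u`, `sigma2_e`, `se_sigma2_u`, `se_sigma2_e`, `loglik`,
#'   `method`, `convergence` (list with `boundary` flag and optimizer
#'   details), and the per-stratum statistics needed by [linear_blups()].
#' @export
#' @examples
#' fit <- fit_linear(c(1, 3, 5, 7), matrix(1, 4, 1), c("A", "A", "B", "B"))
#' c(fit$beta, fit$sigma2_u, fit$sigma2_e)  # 4, 7, 2
fit_linear <- function(y, X, strata, method = c("REML", "ML"),
                       fix_sigma2_u = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(y) != nrow(X)) stop_maihda("y and X dimensions disagree")
  if (length(y) <= ncol(X))
    stop_maihda("need more observations than design columns")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_maihda("singular design matrix; collinear columns: ",
                paste(bad, collapse = ", "))
  }
  ss <- lmm_suffstats(y, X, strata)
  if (sum(ss$present) < 2L) stop_maihda("need at least 2 non-empty strata")
  reml <- method == "REML"
  df <- if (reml) ss$n - ss$p else ss$n

  if (!is.null(fix_sigma2_u)) {
    if (fix_sigma2_u == 0) {
      g <- lmm_gls(ss, 0)
      sigma2_e <- g$Q / df
      if (sigma2_e <= 0) stop_maihda("degenerate outcome: zero residual variance")
      return(lmm_result(ss, psi = 0, g, sigma2_u = 0, sigma2_e, method,
                        boundary = TRUE, iterations = 0L))
    }
    # profile sigma2_e at fixed sigma2_u via 1-D optimisation over sigma2_e
    obj <- function(log_s2e) {
      s2e <- exp(log_s2e)
      lmm_negll(ss, fix_sigma2_u, s2e, reml)
    }
    opt <- optimize(obj, c(-20, 20), tol = 1e-10)
    sigma2_e <- exp(opt$minimum)
    g <- lmm_gls(ss, fix_sigma2_u / sigma2_e)
    return(lmm_result(ss, fix_sigma2_u / sigma2_e, g, fix_sigma2_u,
                      sigma2_e, method, boundary = FALSE, iterations = 1L))
  }

  crit <- function(lp) lmm_criterion(ss, exp(lp), reml)
  opt <- optimize(crit, interval = c(log(1e-10), log(1e6)), tol = 1e-8)
  crit0 <- lmm_criterion(ss, 0, reml)
  boundary <- crit0 <= opt$objective + 1e-9 || opt$minimum <= log(1e-10) + 1e-6
  psi <- if (boundary) 0 else exp(opt$minimum)
  if (!boundary) {
    # polish the optimum to machine precision on the analytic score
    dfun <- function(lp) lmm_criterion_deriv(ss, exp(lp), reml) * exp(lp)
    lo <- opt$minimum - 0.5
    hi <- opt$minimum + 0.5
    if (dfun(lo) < 0 && dfun(hi) > 0) {
      root <- stats::uniroot(dfun, c(lo, hi), tol = 1e-14)
      psi <- exp(root$root)
    }
  }
  g <- lmm_gls(ss, psi)
  sigma2_e <- g$Q / df
  if (sigma2_e <= .Machine$double.eps)
    stop_maihda("degenerate outcome: zero residual variance")
  sigma2_u <- psi * sigma2_e
  lmm_result(ss, psi, g, sigma2_u, sigma2_e, method, boundary,
             iterations = 1L)
}

# Full (non-profiled) -log likelihood in (sigma2_u, sigma2_e); used for the
# reported log-likelihood and for variance-component standard errors.
lmm_negll <- function(ss, sigma2_u, sigma2_e, reml) {
  psi <- sigma2_u / sigma2_e
  g <- lmm_gls(ss, psi)
  n_j <- ss$n_j[ss$present]
  ll <- -0.5 * (ss$n * log(2 * pi * sigma2_e) + sum(log1p(n_j * psi)) +
                g$Q / sigma2_e)
  if (reml)
    ll <- ll - 0.5 * (g$logdetA - ss$p * log(sigma2_e)) +
      0.5 * ss$p * log(2 * pi)
  -ll
}

lmm_result <- function(ss, psi, g, sigma2_u, sigma2_e, method, boundary,
                       iterations) {
  reml <- method == "REML"
  Ainv <- chol2inv(chol(g$A))
  vcov_beta <- sigma2_e * Ainv
  dimnames(vcov_beta) <- list(colnames(ss$XtX), colnames(ss$XtX))
  beta <- setNames(as.numeric(g$beta), colnames(ss$XtX))

  # SEs of the variance components from the numeric Hessian of -loglik.
  se <- c(NA_real_, NA_real_)
  if (sigma2_u > 0) {
    h <- numeric_hessian(function(th) lmm_negll(ss, th[1], th[2], reml),
                         c(sigma2_u, sigma2_e))
    vc <- try(solve(h), silent = TRUE)
    if (!inherits(vc, "try-error") && all(diag(vc) > 0))
      se <- sqrt(diag(vc))
  } else {
    h <- numeric_hessian(function(th) lmm_negll(ss, 0, th[1], reml),
                         sigma2_e)
    if (h[1, 1] > 0) se[2] <- sqrt(1 / h[1, 1])
  }

  # Per-stratum means for BLUPs: mean residual per stratum.
  keep <- ss$present
  n_j_all <- ss$n_j
  ybar <- ifelse(n_j_all > 0, ss$ysum / pmax(n_j_all, 1L), NA_real_)
  xbar <- ss$Xsum / pmax(n_j_all, 1L)
  xbar[n_j_all == 0L, ] <- NA_real_

  structure(
    list(beta = beta, vcov_beta = vcov_beta,
         sigma2_u = sigma2_u, sigma2_e = sigma2_e,
         se_sigma2_u = se[1], se_sigma2_e = se[2],
         loglik = -lmm_negll(ss, sigma2_u, sigma2_e, reml),
         method = method,
         convergence = list(boundary = boundary, iterations = iterations,
                            tolerance = 1e-10, converged = TRUE),
         strata = list(levels = ss$levels, n_j = n_j_all, ybar = ybar,
                       xbar = xbar),
         n = ss$n, p = ss$p),
    class = "maihda_lmm")
}

numeric_hessian <- function(f, x, rel = 1e-4) {
  k <- length(x)
  h <- pmax(abs(x), 1e-4) * rel
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) for (j in i:k) {
    xpp <- x; xpp[i] <- xpp[i] + h[i]; xpp[j] <- xpp[j] + h[j]
    xpm <- x; xpm[i] <- xpm[i] + h[i]; xpm[j] <- xpm[j] - h[j]
    xmp <- x; xmp[i] <- xmp[i] - h[i]; xmp[j] <- xmp[j] + h[j]
    xmm <- x; xmm[i] <- xmm[i] - h[i]; xmm[j] <- xmm[j] - h[j]
    H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) /
      (4 * h[i] * h[j])
  }
  H
}

#' @export
print.maihda_lmm <- function(x, ...) {
  cat("Random-intercept linear model (", x$method, ")\n", sep = "")
  cat(sprintf("  n = %d, strata = %d (non-empty %d)\n", x$n,
              length(x$strata$levels), sum(x$strata$n_j > 0)))
  cat(sprintf("  sigma2_u = %.4f, sigma2_e = %.4f%s\n", x$sigma2_u,
              x$sigma2_e,
              if (x$convergence$boundary) "  [boundary]" else ""))
  print(round(x$beta, 4))
  invisible(x)
}

#' Empirical-Bayes (BLUP) stratum intercepts for a linear fit
#'
#' `u_hat_j = lambda_j * (mean residual of stratum j)` with shrinkage factor
#' `lambda_j = sigma2_u / (sigma2_u + sigma2_e / n_j)`. Intervals use the
#' conditional (comparative) posterior SD
#' `sqrt(sigma2_u * (1 - lambda_j))`. Empty strata get `u_hat = 0` with the
#' prior SD `sqrt(sigma2_u)`.
#'
#' @param fit A [fit_linear()] result.
#' @param level Confidence level for the intervals.
#' @return A `data.frame` with columns `stratum`, `n`, `u_hat`, `post_sd`,
#'   `lower`, `upper`.
#' @export
linear_blups <- function(fit, level = 0.95) {
  st <- fit$strata
  z <- stats::qnorm(1 - (1 - level) / 2)
  resid_mean <- st$ybar - as.numeric(st$xbar %*% fit$beta)
  lambda <- fit$sigma2_u / (fit$sigma2_u + fit$sigma2_e / pmax(st$n_j, 1L))
  lambda[st$n_j == 0L] <- 0
  u_hat <- ifelse(st$n_j > 0, lambda * resid_mean, 0)
  if (fit$sigma2_u == 0) u_hat[] <- 0
  post_sd <- sqrt(fit$sigma2_u * (1 - lambda))
  post_sd[st$n_j == 0L] <- sqrt(fit$sigma2_u)
  data.frame(stratum = st$levels, n = st$n_j, u_hat = u_hat,
             post_sd = post_sd,
             lower = u_hat - z * post_sd, upper = u_hat + z * post_sd,
             stringsAsFactors = FALSE)
}
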