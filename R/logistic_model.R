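# Two-level random-intercept logistic model, maximum likelihood via adaptive
# Gauss-Hermite quadrature over the stratum random intercept.
#
# The marginal likelihood factorises over strata. For each stratum the
# integrand is centred and scaled at the posterior mode (Laplace step), then
# integrated with Gauss-Hermite nodes. Rows that share a stratum and an
# identical design row are collapsed to binomial counts first, which makes
# null and main-effects models (whose covariates are constant within
# stratum) essentially free regardless of n.

# Collapse (stratum, design-row) duplicates to binomial counts.
logistic_collapse <- function(y, X, f) {
  key <- paste(as.integer(f), do.call(paste, c(as.data.frame(X), sep = "\r")),
               sep = "\r")
  u <- !duplicated(key)
  if (sum(u) > 0.6 * length(y)) {
    return(list(X = X, s = y, m = rep(1, length(y)), f = f))
  }
  idx <- match(key, key[u])
  s <- as.numeric(rowsum(y, idx)[, 1])
  m <- as.numeric(rowsum(rep(1, length(y)), idx)[, 1])
  list(X = X[u, , drop = FALSE], s = s, m = m, f = f[u])
}

# Per-stratum posterior modes of u given (beta, sigma), by vectorised Newton.
logistic_modes <- function(eta, s, m, f, sigma2, u0, n_lev) {
  u <- u0
  for (it in 1:50) {
    p <- plogis(eta + u[as.integer(f)])
    g <- as.numeric(rowsum(s - m * p, as.integer(f))) - u / sigma2
    h <- -as.numeric(rowsum(m * p * (1 - p), as.integer(f))) - 1 / sigma2
    step <- g / h
    # dampen large steps for stability
    step <- pmax(pmin(step, 5), -5)
    u <- u - step
    if (max(abs(g)) < 1e-9) break
  }
  p <- plogis(eta + u[as.integer(f)])
  h <- -as.numeric(rowsum(m * p * (1 - p), as.integer(f))) - 1 / sigma2
  list(mode = u, curv = -h)
}

# GHQ log-likelihood and score for (beta, log sigma). `gh` has nodes z and
# weights w (physicists' convention, weight e^{-z^2} included in w).
logistic_ghq <- function(par, dat, gh, env) {
  p <- ncol(dat$X)
  beta <- par[seq_len(p)]
  sigma <- max(exp(par[p + 1L]), 1e-8)
  sigma2 <- sigma^2
  fi <- as.integer(dat$f)
  n_lev <- nlevels(dat$f)
  eta <- as.numeric(dat$X %*% beta)

  md <- logistic_modes(eta, dat$s, dat$m, dat$f, sigma2, env$u0, n_lev)
  env$u0 <- md$mode
  s_j <- 1 / sqrt(md$curv)

  K <- length(gh$z)
  a <- matrix(0, n_lev, K)       # log integrand contributions per node
  for (k in seq_len(K)) {
    u_k <- md$mode + sqrt(2) * s_j * gh$z[k]
    eta_k <- eta + u_k[fi]
    ll_rows <- dat$s * eta_k - dat$m * log1pexp(eta_k)
    lj <- as.numeric(rowsum(ll_rows, fi))
    a[, k] <- log(gh$w[k]) + gh$z[k]^2 + lj -
      u_k^2 / (2 * sigma2)
  }
  lse <- row_logsumexp(a)
  base <- log(sqrt(2) * s_j) - 0.5 * log(2 * pi * sigma2)
  ll_j <- base + lse
  ll <- sum(ll_j)

  # Score via posterior node weights (Fisher's identity applied to the
  # quadrature representation; nodes treated as fixed).
  wpost <- exp(a - lse)               # n_lev x K, rows sum to 1
  gbeta <- numeric(p)
  gls <- 0
  for (k in seq_len(K)) {
    u_k <- md$mode + sqrt(2) * s_j * gh$z[k]
    p_k <- plogis(eta + u_k[fi])
    r_k <- (dat$s - dat$m * p_k) * wpost[fi, k]
    gbeta <- gbeta + as.numeric(crossprod(dat$X, r_k))
    gls <- gls + sum(wpost[, k] * (u_k^2 / sigma2 - 1))
  }
  list(ll = ll, grad = c(gbeta, gls))
}

#' Fit a two-level random-intercept logistic model
#'
#' `logit P(y_ij = 1) = x_ij' beta + u_j`, `u_j ~ N(0, sigma2_u)` on the
#' latent logit scale. Maximum likelihood via adaptive Gauss-Hermite
#' quadrature (default order 15) over the stratum random intercept; the
#' boundary estimate `sigma2_u = 0` is allowed and flagged.
#'
#' @param y Binary 0/1 outcome vector.
#' @param X Design matrix including an intercept column.
#' @param strata Stratum identifier per record; empty levels retained.
#' @param quadrature_order Number of Gauss-Hermite nodes (default 15).
#' @param fix_sigma2_u Optionally fix the level-2 variance; `0` reduces to
#'   ordinary logistic regression (fitted by the same Newton machinery).
#' @param max_iter Maximum BFGS iterations.
#' @return An object of class `maihda_glmm` with `beta`, `vcov_beta`,
#'   odds-ratio table `or` (exponentiated Wald intervals), `sigma2_u`,
#'   `se_sigma2_u`, `loglik`, `quadrature_order`, `convergence`, and the
#'   per-stratum data needed by [logistic_eb_intercepts()].
#' @export
fit_logistic <- function(y, X, strata, quadrature_order = 15,
                         fix_sigma2_u = NULL, max_iter = 400) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!all(y %in% c(0, 1))) stop_maihda("y must be binary 0/1")
  f <- if (is.factor(strata)) strata else factor(strata)
  if (sum(table(f) > 0) < 2L && is.null(fix_sigma2_u))
    stop_maihda("need at least 2 non-empty strata")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_maihda("singular design matrix; collinear columns: ",
                paste(bad, collapse = ", "))
  }
  dat <- logistic_collapse(y, X, f)
  dat$f <- droplevels(dat$f)    # empty levels re-attached for EB output
  p <- ncol(X)
  xsd <- apply(X, 2, sd)
  xscale <- ifelse(xsd > 0, xsd, 1)

  # Plain (no random effect) logistic fit: starting values, and the full
  # answer when sigma2_u is fixed at zero.
  plain <- glm_newton(dat)
  check_separation(plain$beta, xscale)
  if (!is.null(fix_sigma2_u) && fix_sigma2_u == 0) {
    return(glmm_result(plain$beta, plain$vcov, sigma2_u = 0,
                       se_sigma2_u = NA_real_, loglik = plain$ll,
                       quadrature_order, boundary = TRUE, counts = 0L,
                       dat = dat, f = f, X = X, y = y))
  }

  gh0 <- pracma::gaussHermite(quadrature_order)
  gh <- list(z = gh0$x, w = gh0$w)
  env <- new.env()
  env$u0 <- numeric(nlevels(dat$f))

  negll <- function(par) -logistic_ghq(par, dat, gh, env)$ll
  neggr <- function(par) -logistic_ghq(par, dat, gh, env)$grad

  # log sigma is bounded below: at the bound sigma2_u < 1e-6 and the fit is
  # declared a boundary (sigma2_u = 0) fit.
  ls_floor <- log(1e-4)
  fixed_sigma <- !is.null(fix_sigma2_u)
  if (fixed_sigma) {
    ls_fix <- 0.5 * log(fix_sigma2_u)
    negll_b <- function(b) negll(c(b, ls_fix))
    neggr_b <- function(b) neggr(c(b, ls_fix))[seq_len(p)]
    opt <- optim(plain$beta, negll_b, neggr_b, method = "BFGS",
                 control = list(maxit = max_iter, reltol = 1e-12))
    par <- c(opt$par, ls_fix)
  } else {
    start <- c(plain$beta, log(0.3))
    opt <- optim(start, negll, neggr, method = "L-BFGS-B",
                 lower = c(rep(-Inf, p), ls_floor),
                 control = list(maxit = max_iter, factr = 1e6))
    if (opt$convergence == 52 && opt$par[p + 1L] < ls_floor + 0.5) {
      # line search stalled while sigma ran into its floor: finish as a
      # boundary fit with sigma fixed at the floor
      negll_b <- function(b) negll(c(b, ls_floor))
      neggr_b <- function(b) neggr(c(b, ls_floor))[seq_len(p)]
      opt <- optim(opt$par[seq_len(p)], negll_b, neggr_b, method = "BFGS",
                   control = list(maxit = max_iter, reltol = 1e-12))
      opt$par <- c(opt$par, ls_floor)
    }
    par <- opt$par
  }
  if (opt$convergence != 0)
    stop_maihda("logistic model did not converge after ", max_iter,
                " iterations (optim code ", opt$convergence, ")")
  beta <- unname(par[seq_len(p)])
  check_separation(beta, xscale)
  sigma2_u <- unname(exp(par[p + 1L])^2)
  boundary <- !fixed_sigma && sigma2_u < 1e-6
  if (boundary) sigma2_u <- 0

  # Observed information via finite differences of the analytic score.
  act <- if (fixed_sigma || boundary) seq_len(p) else seq_len(p + 1L)
  gfun <- function(q) {
    full <- par
    full[act] <- q
    neggr(full)[act]
  }
  H <- jacobian_fd(gfun, par[act])
  H <- (H + t(H)) / 2
  vc <- try(solve(H), silent = TRUE)
  if (inherits(vc, "try-error"))
    vc <- matrix(NA_real_, length(act), length(act))
  vcov_beta <- vc[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  se_sigma2_u <- if (!fixed_sigma && !boundary && is.finite(vc[p + 1, p + 1]) &&
                     vc[p + 1, p + 1] > 0) {
    # delta method from log sigma to sigma^2: d sigma2 / d log sigma = 2 sigma2
    2 * sigma2_u * sqrt(vc[p + 1, p + 1])
  } else NA_real_

  glmm_result(setNames(beta, colnames(X)), vcov_beta, sigma2_u, se_sigma2_u,
              loglik = -negll(par), quadrature_order, boundary,
              counts = opt$counts[[1]], dat = dat, f = f, X = X, y = y)
}

# Divergent coefficients on the standardized scale indicate separation: the
# overall norm exceeding 50, or any single scaled coefficient exceeding 25
# (a log-odds shift no non-separated binary fit can produce).
check_separation <- function(beta, xscale) {
  sc <- beta * xscale
  if (sqrt(sum(sc^2)) > 50 || max(abs(sc)) > 25)
    stop_maihda("separation detected: diverging coefficient estimates")
}

# Newton-Raphson for plain binomial logistic regression on collapsed data.
glm_newton <- function(dat, tol = 1e-12, max_iter = 100) {
  p <- ncol(dat$X)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(dat$X %*% beta)
    mu <- plogis(eta)
    g <- as.numeric(crossprod(dat$X, dat$s - dat$m * mu))
    W <- dat$m * mu * (1 - mu)
    H <- crossprod(dat$X * sqrt(pmax(W, 1e-12)))
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    beta <- beta + step
    if (sum(abs(step)) < tol || max(abs(beta)) > 1e3) break
  }
  eta <- as.numeric(dat$X %*% beta)
  ll <- sum(dat$s * eta - dat$m * log1pexp(eta))
  list(beta = beta, vcov = solve(H), ll = ll)
}

jacobian_fd <- function(g, x, rel = 1e-6) {
  k <- length(x)
  J <- matrix(0, k, k)
  for (i in seq_len(k)) {
    h <- pmax(abs(x[i]), 1) * rel
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    J[, i] <- (g(xp) - g(xm)) / (2 * h)
  }
  J
}

glmm_result <- function(beta, vcov_beta, sigma2_u, se_sigma2_u, loglik,
                        quadrature_order, boundary, counts, dat, f, X, y) {
  se <- sqrt(pmax(diag(vcov_beta), 0))
  or <- data.frame(
    term = names(beta), estimate = unname(beta), se = se,
    or = exp(unname(beta)),
    or_lower = exp(unname(beta) - 1.959963984540054 * se),
    or_upper = exp(unname(beta) + 1.959963984540054 * se),
    stringsAsFactors = FALSE)
  structure(
    list(beta = beta, vcov_beta = vcov_beta, or = or,
         sigma2_u = sigma2_u, se_sigma2_u = se_sigma2_u,
         loglik = loglik, quadrature_order = quadrature_order,
         convergence = list(boundary = boundary, evaluations = counts,
                            converged = TRUE),
         data = list(dat = dat, f = f),
         n = length(y), p = ncol(X)),
    class = "maihda_glmm")
}

#' @export
print.maihda_glmm <- function(x, ...) {
  cat("Random-intercept logistic model (adaptive GHQ, order ",
      x$quadrature_order, ")\n", sep = "")
  cat(sprintf("  n = %d, strata = %d; sigma2_u = %.4f%s\n", x$n,
              nlevels(x$data$f), x$sigma2_u,
              if (x$convergence$boundary) "  [boundary]" else ""))
  print(x$or[, c("term", "or", "or_lower", "or_upper")], digits = 4,
        row.names = FALSE)
  invisible(x)
}

#' Empirical-Bayes stratum intercepts for a logistic fit
#'
#' Per-stratum posterior mode of the random intercept with SD from the
#' curvature at the mode (Laplace approximation); 95% interval
#' `mode +/- z * SD`. Empty strata get 0 with the prior SD
#' `sqrt(sigma2_u)`; with `sigma2_u = 0` all intercepts are exactly 0.
#'
#' @param fit A [fit_logistic()] result.
#' @param level Confidence level.
#' @return A `data.frame` with `stratum`, `n`, `u_hat`, `post_sd`, `lower`,
#'   `upper`.
#' @export
logistic_eb_intercepts <- function(fit, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  dat <- fit$data$dat
  lev_all <- levels(fit$data$f)
  n_all <- as.integer(table(fit$data$f))
  if (fit$sigma2_u == 0) {
    return(data.frame(stratum = lev_all, n = n_all, u_hat = 0, post_sd = 0,
                      lower = 0, upper = 0, stringsAsFactors = FALSE))
  }
  eta <- as.numeric(dat$X %*% fit$beta)
  md <- logistic_modes(eta, dat$s, dat$m, dat$f, fit$sigma2_u,
                       numeric(nlevels(dat$f)), nlevels(dat$f))
  u <- setNames(numeric(length(lev_all)), lev_all)
  sdv <- setNames(rep(sqrt(fit$sigma2_u), length(lev_all)), lev_all)
  u[levels(dat$f)] <- md$mode
  sdv[levels(dat$f)] <- 1 / sqrt(md$curv)
  empty <- n_all == 0L
  u[empty] <- 0
  sdv[empty] <- sqrt(fit$sigma2_u)
  data.frame(stratum = lev_all, n = n_all, u_hat = unname(u),
             post_sd = unname(sdv),
             lower = unname(u - z * sdv), upper = unname(u + z * sdv),
             stringsAsFactors = FALSE)
}
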