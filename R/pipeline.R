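# End-to-end orchestration: per sex and outcome, Models 1 -> 3, variance
# decomposition, predictions, ranked tables, serialization.
#
# Model sequence:
#   Model 1 (null)        : intercept + stratum random intercept
#   Model 2 (main effects): + the five behaviour codes used to build strata
#   Model 3 (+confounders): + centred age and TDI, ethnicity, employment

#' Analysis configuration
#'
#' @param input Path to a CSV in the documented raw-questionnaire dialect, or
#'   a `data.frame` of raw records.
#' @param outcome One of `"bmi"` (linear), `"obesity-vs-normal"` or
#'   `"overweight-vs-normal"` (logistic). May be a vector to run several.
#' @param sexes Subset of `c("male", "female")`.
#' @param models Subset of `1:3`; model 3 requires confounder columns.
#' @param method Linear estimation method, `"REML"` or `"ML"`.
#' @param quadrature Gauss-Hermite order for logistic fits.
#' @param prediction_model Which fitted model the stratum-prediction tables
#'   use (default the largest requested, as in confounder-adjusted reports).
#' @param outdir Optional output directory for [write_report()].
#' @param seed Seed for any stochastic diagnostics (the pipeline itself is
#'   deterministic).
#' @return An object of class `maihda_analysis_config`.
#' @export
maihda_config <- function(input, outcome = "bmi",
                          sexes = c("male", "female"), models = 1:3,
                          method = c("REML", "ML"), quadrature = 15,
                          prediction_model = max(models), outdir = NULL,
                          seed = 1L) {
  method <- match.arg(method)
  outcome <- match.arg(outcome,
                       c("bmi", "obesity-vs-normal", "overweight-vs-normal"),
                       several.ok = TRUE)
  if (!all(models %in% 1:3)) stop_maihda("models must be a subset of 1:3")
  if (!all(sexes %in% c("male", "female")))
    stop_maihda("sexes must be a subset of male/female")
  if (!prediction_model %in% models)
    stop_maihda("prediction_model must be one of the requested models")
  structure(list(input = input, outcome = outcome, sexes = sexes,
                 models = sort(unique(models)), method = method,
                 quadrature = quadrature,
                 prediction_model = prediction_model,
                 outdir = outdir, seed = as.integer(seed)),
            class = "maihda_analysis_config")
}

#' Centre covariate columns at their means
#'
#' @param X Matrix or data.frame.
#' @param columns Column names to centre.
#' @return List with `X` (centred) and `centers` (named means).
#' @export
center_covariates <- function(X, columns) {
  missing_cols <- setdiff(columns, colnames(X))
  if (length(missing_cols))
    stop_maihda("missing columns: ", paste(missing_cols, collapse = ", "))
  centers <- setNames(numeric(length(columns)), columns)
  for (cn in columns) {
    if (!is.numeric(X[, cn])) stop_maihda("column not numeric: ", cn)
    centers[cn] <- mean(X[, cn])
    X[, cn] <- X[, cn] - centers[cn]
  }
  list(X = X, centers = centers)
}

MODEL2_TERMS <- c("sleep_meets", "fv_meets", "alcohol_meets", "pa_meets",
                  "smoking_current", "smoking_never")
MODEL3_TERMS <- c(MODEL2_TERMS, "age_c", "tdi_c", "nonwhite", "notemployed")

# Design matrix for a model number; `centers` from the analysis set (per sex,
# post-exclusion). Returns the matrix plus the centring values used.
build_design <- function(coded, model, centers = NULL) {
  n <- nrow(coded)
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (model >= 2) {
    X <- cbind(X,
               sleep_meets = coded$sleep_meets, fv_meets = coded$fv_meets,
               alcohol_meets = coded$alcohol_meets, pa_meets = coded$pa_meets,
               smoking_current = as.integer(coded$smoking_code == 1L),
               smoking_never = as.integer(coded$smoking_code == 2L))
  }
  if (model >= 3) {
    need <- c("age", "tdi", "ethnicity", "employment")
    miss <- need[!need %in% names(coded) |
                   vapply(need, function(v) all(is.na(coded[[v]])), TRUE)]
    if (length(miss))
      stop_maihda("model 3 requires confounder columns: ",
                  paste(miss, collapse = ", "))
    Xc <- cbind(age_c = coded$age, tdi_c = coded$tdi)
    if (is.null(centers)) {
      cc <- center_covariates(Xc, c("age_c", "tdi_c"))
      Xc <- cc$X
      centers <- cc$centers
    } else {
      Xc[, "age_c"] <- Xc[, "age_c"] - centers[["age_c"]]
      Xc[, "tdi_c"] <- Xc[, "tdi_c"] - centers[["tdi_c"]]
    }
    X <- cbind(X, Xc,
               nonwhite = as.integer(coded$ethnicity != "white"),
               notemployed = as.integer(coded$employment != "employed"))
  }
  list(X = X, centers = centers)
}

# Design rows for empty strata: behaviour codes decoded from the key,
# confounders at their centring values (0 after centring).
empty_stratum_design <- function(model, columns) {
  keys <- enumerate_strata()
  full <- t(vapply(keys, function(k) {
    d <- decode_stratum(k)
    c(intercept = 1,
      sleep_meets = d$sleep_meets, fv_meets = d$fv_meets,
      alcohol_meets = d$alcohol_meets, pa_meets = d$pa_meets,
      smoking_current = as.integer(d$smoking_code == 1L),
      smoking_never = as.integer(d$smoking_code == 2L),
      age_c = 0, tdi_c = 0, nonwhite = 0, notemployed = 0)
  }, numeric(11)))
  rownames(full) <- keys
  full[, columns, drop = FALSE]
}

#' Run the full MAIHDA analysis
#'
#' For each requested sex and outcome: guideline recoding, the exclusion
#' cascade, stratum assignment, Models 1-3 (linear for BMI, random-intercept
#' logistic for the binary contrasts), VPC and PCV, empirical-Bayes stratum
#' predictions with interaction flags, ranked strata, and collinearity
#' diagnostics. A failing cell is recorded with its error; other cells
#' proceed. The report is a pure function of the input data and the
#' configuration.
#'
#' @param config A [maihda_config()].
#' @return An object of class `maihda_report`: per-cell results under
#'   `cells[["<sex>:<outcome>"]]`, plus `config` and a provenance block.
#' @export
run_maihda <- function(config) {
  if (!inherits(config, "maihda_analysis_config"))
    stop_maihda("config must come from maihda_config()")
  raw <- if (is.character(config$input)) read.csv(config$input,
                                                  stringsAsFactors = FALSE)
         else as.data.frame(config$input)
  coded_all <- recode_behaviours(raw)

  cells <- list()
  for (s in config$sexes) {
    coded_sex <- coded_all[coded_all$sex == s, , drop = FALSE]
    for (oc in config$outcome) {
      cell_id <- paste(s, oc, sep = ":")
      cells[[cell_id]] <- tryCatch(
        run_cell(coded_sex, s, oc, config),
        error = function(e) {
          list(error = conditionMessage(e), sex = s, outcome = oc)
        })
    }
  }
  structure(
    list(cells = cells, config = config,
         provenance = list(
           package_version = as.character(utils::packageVersion("maihda")),
           n_input = nrow(raw))),
    class = "maihda_report")
}

run_cell <- function(coded_sex, sex, outcome, config) {
  if (3 %in% config$models) {
    need <- c("age", "tdi", "ethnicity", "employment")
    miss <- need[vapply(need, function(v)
      is.null(coded_sex[[v]]) || all(is.na(coded_sex[[v]])), TRUE)]
    if (length(miss))
      stop_maihda("model 3 requires confounder columns: ",
                  paste(miss, collapse = ", "))
  }
  contrast <- if (outcome == "bmi") "bmi-linear" else outcome
  excl <- apply_exclusions(coded_sex, contrast)
  data <- excl$data
  if (!nrow(data)) stop_maihda("no records retained for ", sex, ":", outcome)
  idx <- assign_strata(data)
  f <- attr(idx, "assignment")
  logistic <- outcome != "bmi"
  y <- if (!logistic) data$bmi
       else as.integer(data$weight_status ==
                       if (outcome == "obesity-vs-normal") "obese"
                       else "overweight")

  centers <- NULL
  fits <- list(); designs <- list()
  for (m in config$models) {
    d <- build_design(data, m, centers)
    if (m >= 3 && is.null(centers)) centers <- d$centers
    designs[[as.character(m)]] <- d$X
    fits[[as.character(m)]] <-
      if (logistic) fit_logistic(y, d$X, f, config$quadrature)
      else fit_linear(y, d$X, f, config$method)
  }

  # variance decomposition across the model sequence
  null_id <- as.character(min(config$models))
  sigma_null <- fits[[null_id]]$sigma2_u
  summary_rows <- lapply(config$models, function(m) {
    ft <- fits[[as.character(m)]]
    vpc <- if (logistic) compute_vpc(ft$sigma2_u, family = "logistic")
           else compute_vpc(ft$sigma2_u, ft$sigma2_e)
    pcv <- if (m == min(config$models)) 0
           else as.numeric(compute_pcv(sigma_null, ft$sigma2_u))
    data.frame(model = m, sigma2_u = ft$sigma2_u,
               sigma2_e = if (logistic) logistic_latent_variance()
                          else ft$sigma2_e,
               vpc_pct = vpc, pcv_pct = pcv,
               loglik = ft$loglik,
               boundary = ft$convergence$boundary,
               stringsAsFactors = FALSE)
  })
  maihda_summary <- do.call(rbind, summary_rows)

  pm <- as.character(config$prediction_model)
  fit_pred <- fits[[pm]]
  intercepts <- if (logistic) logistic_eb_intercepts(fit_pred)
                else linear_blups(fit_pred)
  Xp <- designs[[pm]]
  preds <- predict_strata(fit_pred, y, Xp, f, intercepts,
                          empty_design = empty_stratum_design(
                            as.integer(pm), colnames(Xp)))
  preds <- flag_interactions(preds)
  ranks <- rank_strata(preds, k = 5)

  diag <- NULL
  max_m <- max(config$models)
  if (max_m >= 2) {
    Xd <- designs[[as.character(max_m)]]
    diag <- collinearity_diagnostics(Xd[, colnames(Xd) != "intercept",
                                        drop = FALSE])
  }

  list(sex = sex, outcome = outcome, n = nrow(data),
       ledger = excl$ledger, stratum_index = idx, centers = centers,
       fits = fits, summary = maihda_summary, predictions = preds,
       ranked = ranks, collinearity = diag)
}

#' @export
print.maihda_report <- function(x, ...) {
  cat("MAIHDA report:", length(x$cells), "analysis cell(s)\n")
  for (id in names(x$cells)) {
    cell <- x$cells[[id]]
    if (!is.null(cell$error)) {
      cat("  ", id, ": ERROR - ", cell$error, "\n", sep = "")
    } else {
      v <- cell$summary
      cat(sprintf("  %s: n = %d; VPC%% by model: %s\n", id, cell$n,
                  paste(sprintf("%d=%.2f", v$model, v$vpc_pct),
                        collapse = ", ")))
    }
  }
  invisible(x)
}

#' Serialize a MAIHDA report
#'
#' Writes the coefficient/variance tables and ranked-strata tables as CSV and
#' the full report bundle as JSON. Output is deterministic for a given input
#' and configuration.
#'
#' @param report A [run_maihda()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir = report$config$outdir) {
  if (is.null(dir)) stop_maihda("no output directory given")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  bundle <- list(provenance = report$provenance, cells = list())
  for (id in names(report$cells)) {
    cell <- report$cells[[id]]
    slug <- gsub("[^a-z0-9]+", "_", id)
    if (!is.null(cell$error)) {
      bundle$cells[[id]] <- list(error = cell$error)
      next
    }
    coefs <- do.call(rbind, lapply(names(cell$fits), function(m) {
      ft <- cell$fits[[m]]
      data.frame(model = as.integer(m), term = names(ft$beta),
                 estimate = unname(ft$beta),
                 se = sqrt(pmax(diag(ft$vcov_beta), 0)),
                 stringsAsFactors = FALSE)
    }))
    p1 <- file.path(dir, paste0(slug, "_coefficients.csv"))
    write.csv(coefs, p1, row.names = FALSE)
    p2 <- file.path(dir, paste0(slug, "_summary.csv"))
    write.csv(cell$summary, p2, row.names = FALSE)
    # display precision: BMI to 1 decimal, probabilities to 2; the flags were
    # computed on unrounded values before this point
    strata_tab <- cell$ranked$ranked
    dp <- if (cell$outcome == "bmi") 1L else 2L
    num_cols <- c("observed", "incl_est", "incl_lower", "incl_upper",
                  "excl_est", "excl_lower", "excl_upper")
    strata_tab[num_cols] <- lapply(strata_tab[num_cols], round, digits = dp)
    u_cols <- c("u_hat", "u_lower", "u_upper")
    strata_tab[u_cols] <- lapply(strata_tab[u_cols], round, digits = 2L)
    p3 <- file.path(dir, paste0(slug, "_strata.csv"))
    write.csv(strata_tab, p3, row.names = FALSE, quote = TRUE)
    paths <- c(paths, p1, p2, p3)
    bundle$cells[[id]] <- list(
      n = cell$n, ledger = unclass(cell$ledger),
      summary = cell$summary, coefficients = coefs,
      centers = as.list(cell$centers %||% list()),
      strata = cell$ranked$ranked)
  }
  pj <- file.path(dir, "maihda_report.json")
  jsonlite::write_json(bundle, pj, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(paths, pj))
}
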