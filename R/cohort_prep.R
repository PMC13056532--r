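# Guideline recoding, weight-status classification, exclusion cascade and
# descriptive / collinearity diagnostics.
#
# Guidelines (UK public-health recommendations):
#   sleep    : 7-9 hours per day (both boundaries meet)
#   fruit&veg: at least 5 portions per day
#   alcohol  : no more than 14 units per week (14 meets)
#   activity : at least 150 min moderate OR 75 min vigorous per week
#   smoking  : current / previous / never (three categories, not binary)

#' Recode raw lifestyle measures against public-health guidelines
#'
#' Converts raw questionnaire-scale measures into guideline-adherence codes.
#' Missingness is data, not an error: a missing input yields a missing code.
#'
#' @param raw A `data.frame` with (any of) columns `sleep_hours`,
#'   `fv_portions`, `alcohol_units`, `pa_moderate_min`, `pa_vigorous_min`,
#'   `smoking` (`"current"`/`"previous"`/`"never"`), and pass-through columns
#'   `sex`, `age`, `tdi`, `ethnicity`, `employment`, `bmi`.
#' @return A `data.frame` of coded records: `sleep_meets`, `fv_meets`,
#'   `alcohol_meets`, `pa_meets` (0/1), `smoking_code` (0 = previous,
#'   1 = current, 2 = never), pass-through confounders, `bmi` and
#'   `weight_status`.
#' @export
recode_behaviours <- function(raw) {
  raw <- as.data.frame(raw)
  n <- nrow(raw)
  col <- function(nm) if (nm %in% names(raw)) raw[[nm]] else rep(NA, n)

  sleep <- col("sleep_hours")
  fv <- col("fv_portions")
  alc <- col("alcohol_units")
  pam <- col("pa_moderate_min")
  pav <- col("pa_vigorous_min")
  smoking <- as.character(col("smoking"))

  bad <- !is.na(smoking) & !smoking %in% names(SMOKING_CODES)
  if (any(bad))
    stop_maihda("unknown smoking category: ", smoking[bad][1])

  # PA is met if either threshold is reached; if one component is missing but
  # the other already meets its threshold, adherence is determined.
  pa_meets <- ifelse(!is.na(pam) & pam >= 150, 1L,
              ifelse(!is.na(pav) & pav >= 75, 1L,
              ifelse(is.na(pam) | is.na(pav), NA_integer_, 0L)))

  bmi <- col("bmi")
  ws <- rep(NA_character_, n)
  ok <- !is.na(bmi)
  if (any(ok)) ws[ok] <- classify_weight_status(bmi[ok])

  out <- data.frame(
    sex = as.character(col("sex")),
    sleep_meets = ifelse(is.na(sleep), NA_integer_,
                         as.integer(sleep >= 7 & sleep <= 9)),
    fv_meets = ifelse(is.na(fv), NA_integer_, as.integer(fv >= 5)),
    alcohol_meets = ifelse(is.na(alc), NA_integer_, as.integer(alc <= 14)),
    pa_meets = pa_meets,
    smoking_code = unname(SMOKING_CODES[smoking]),
    age = as.numeric(col("age")),
    tdi = as.numeric(col("tdi")),
    ethnicity = as.character(col("ethnicity")),
    employment = as.character(col("employment")),
    bmi = as.numeric(bmi),
    weight_status = ws,
    stringsAsFactors = FALSE
  )
  if ("obese" %in% names(raw)) out$obese <- raw$obese
  out
}

#' Classify weight status from BMI
#'
#' Half-open categories partitioning (0, Inf): underweight `[0, 18.5)`,
#' normal `[18.5, 25)`, overweight `[25, 30)`, obese `[30, Inf)`. The 30.0
#' boundary is classified as obese (WHO convention).
#'
#' @param bmi Numeric vector of BMI values in kg/m^2; must be finite and
#'   positive.
#' @return Character vector of `"underweight"`, `"normal"`, `"overweight"`,
#'   `"obese"`.
#' @export
#' @examples
#' classify_weight_status(c(18.5, 24.9, 30))
classify_weight_status <- function(bmi) {
  if (!is.numeric(bmi) || any(!is.finite(bmi)) || any(bmi <= 0))
    stop_maihda("bmi must be finite and positive")
  cut_pts <- c(0, 18.5, 25, 30, Inf)
  labs <- c("underweight", "normal", "overweight", "obese")
  as.character(cut(bmi, breaks = cut_pts, labels = labs, right = FALSE))
}

EXCLUSION_REASONS <- c("missing_lifestyle", "missing_confounders",
                       "missing_bmi", "underweight", "contrast")

#' Apply the exclusion cascade
#'
#' Drops records in a fixed documented order, each record under the first
#' applicable reason: (1) missing lifestyle codes, (2) missing confounders,
#' (3) missing BMI, (4) underweight, (5) for binary contrasts, the weight
#' category not in the contrast.
#'
#' @param coded Coded records from [recode_behaviours()].
#' @param contrast One of `"bmi-linear"` (keeps normal, overweight and obese),
#'   `"obesity-vs-normal"` or `"overweight-vs-normal"`.
#' @return A list with `data` (the retained analysis set) and `ledger`
#'   (class `exclusion_ledger`: per-reason counts, input and retained totals).
#' @export
apply_exclusions <- function(coded,
                             contrast = c("bmi-linear", "obesity-vs-normal",
                                          "overweight-vs-normal")) {
  contrast <- match.arg(contrast)
  if (nrow(coded) == 0L) stop_maihda("empty input: no records to process")

  lifestyle <- c("sleep_meets", "fv_meets", "alcohol_meets", "pa_meets",
                 "smoking_code")
  confounders <- c("age", "tdi", "ethnicity", "employment")

  reason <- rep(NA_character_, nrow(coded))
  miss_any <- function(cols) Reduce(`|`, lapply(cols, function(c) is.na(coded[[c]])))

  mark <- function(cond, why) {
    hit <- is.na(reason) & cond
    reason[hit] <<- why
  }
  mark(miss_any(lifestyle), "missing_lifestyle")
  mark(miss_any(confounders), "missing_confounders")
  mark(is.na(coded$bmi), "missing_bmi")
  mark(!is.na(coded$weight_status) & coded$weight_status == "underweight",
       "underweight")
  drop_cat <- switch(contrast,
    "bmi-linear" = character(0),
    "obesity-vs-normal" = "overweight",
    "overweight-vs-normal" = "obese")
  if (length(drop_cat))
    mark(coded$weight_status %in% drop_cat, "contrast")

  kept <- is.na(reason)
  counts <- vapply(EXCLUSION_REASONS,
                   function(r) sum(reason == r, na.rm = TRUE), integer(1))
  ledger <- structure(
    list(input = nrow(coded), retained = sum(kept), reasons = counts,
         contrast = contrast),
    class = "exclusion_ledger")
  stopifnot(ledger$input == ledger$retained + sum(ledger$reasons))
  list(data = coded[kept, , drop = FALSE], ledger = ledger)
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat("Exclusion ledger (", x$contrast, "): input ", x$input,
      " -> retained ", x$retained, "\n", sep = "")
  for (r in names(x$reasons))
    cat(sprintf("  %-20s %d\n", r, x$reasons[[r]]))
  invisible(x)
}

#' Descriptive summary table by sex
#'
#' Per sex: N and percentage per categorical level (lifestyle behaviours,
#' ethnicity, employment, weight status), mean (SD) for age and TDI, and
#' median (IQR) for BMI. Percentages are rounded to one decimal.
#'
#' @param coded Coded records (typically a post-exclusion analysis set).
#' @return A long `data.frame` with columns `sex`, `variable`, `level`, `n`,
#'   `percent`, `mean`, `sd`, `median`, `q1`, `q3`.
#' @export
descriptive_table <- function(coded) {
  sexes <- sort(unique(coded$sex))
  if (!length(sexes)) stop_maihda("no records")
  rows <- list()
  cat_vars <- list(
    smoking = factor(names(SMOKING_CODES)[match(coded$smoking_code,
                                                SMOKING_CODES)],
                     levels = c("current", "previous", "never")),
    fruit_veg = factor(ifelse(coded$fv_meets == 1, "meets", "not-meets"),
                       levels = c("not-meets", "meets")),
    physical_activity = factor(ifelse(coded$pa_meets == 1, "meets", "not-meets"),
                               levels = c("not-meets", "meets")),
    alcohol = factor(ifelse(coded$alcohol_meets == 1, "meets", "not-meets"),
                     levels = c("not-meets", "meets")),
    sleep = factor(ifelse(coded$sleep_meets == 1, "meets", "not-meets"),
                   levels = c("not-meets", "meets")),
    ethnicity = factor(coded$ethnicity),
    employment = factor(coded$employment),
    weight_status = factor(coded$weight_status,
                           levels = c("underweight", "normal", "overweight",
                                      "obese"))
  )
  for (s in sexes) {
    in_sex <- coded$sex == s
    n_sex <- sum(in_sex)
    if (n_sex == 0L) stop_maihda("empty sex stratum: ", s)
    for (v in names(cat_vars)) {
      f <- cat_vars[[v]][in_sex]
      tab <- table(f[!is.na(f)])
      for (lv in names(tab)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sex = s, variable = v, level = lv, n = as.integer(tab[[lv]]),
          percent = round(100 * tab[[lv]] / sum(tab), 1),
          mean = NA_real_, sd = NA_real_, median = NA_real_,
          q1 = NA_real_, q3 = NA_real_, stringsAsFactors = FALSE)
      }
    }
    for (v in c("age", "tdi")) {
      x <- coded[[v]][in_sex]
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s, variable = v, level = "", n = sum(!is.na(x)),
        percent = NA_real_, mean = mean(x, na.rm = TRUE),
        sd = sd(x, na.rm = TRUE), median = NA_real_,
        q1 = NA_real_, q3 = NA_real_, stringsAsFactors = FALSE)
    }
    b <- coded$bmi[in_sex]
    qs <- quantile(b, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      sex = s, variable = "bmi", level = "", n = sum(!is.na(b)),
      percent = NA_real_, mean = NA_real_, sd = NA_real_,
      median = qs[2], q1 = qs[1], q3 = qs[3], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Collinearity diagnostics for a design matrix
#'
#' Pairwise correlations and per-predictor variance inflation factors,
#' VIF_k = 1 / (1 - R^2_k) where R^2_k comes from regressing predictor k on
#' all the others (with an intercept). Exactly collinear predictors get an
#' infinite VIF and are flagged.
#'
#' @param X Numeric matrix or data.frame of predictors (an intercept /
#'   constant column, if present, is excluded from the diagnostics).
#' @return A list with `correlations` (matrix), `vif` (named vector),
#'   `max_vif`, and `flagged` (names of exactly collinear predictors).
#' @export
collinearity_diagnostics <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- apply(X, 2L, function(col) sd(col) > 0)
  X <- X[, keep, drop = FALSE]
  p <- ncol(X)
  if (p < 2L) stop_maihda("need at least 2 non-constant predictors")
  if (nrow(X) <= p) stop_maihda("need more observations than predictors")
  cors <- stats::cor(X)
  vif <- numeric(p)
  names(vif) <- colnames(X)
  for (k in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    ssr <- sum(fit$residuals^2)
    sst <- sum((X[, k] - mean(X[, k]))^2)
    r2 <- 1 - ssr / sst
    vif[k] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  list(correlations = cors, vif = vif, max_vif = max(vif),
       flagged = names(vif)[is.infinite(vif)])
}
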