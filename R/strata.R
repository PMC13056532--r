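# Behaviour-combination strata: 5-digit keys over
# (sleep, fruit&veg, alcohol, physical activity, smoking).
#
# Digits 1-4 are 0/1 (guideline not met / met); digit 5 is the smoking code
# 0 = previous, 1 = current, 2 = never. The digit order is fixed by the
# convention that "01112" means: sleep not met, fruit&veg met, alcohol met,
# physical activity met, never smoker.

BEHAVIOURS <- c("sleep", "fv", "alcohol", "pa", "smoking")
BEHAVIOUR_LABELS <- c(
  sleep = "sleep duration", fv = "fruit & vegetable intake",
  alcohol = "alcohol intake", pa = "physical activity", smoking = "smoking"
)
SMOKING_CODES <- c(previous = 0L, current = 1L, never = 2L)

#' Enumerate all 48 lifestyle strata
#'
#' Returns every valid 5-digit stratum key exactly once, in lexicographic
#' (equivalently numeric) order. There are 2 x 2 x 2 x 2 x 3 = 48 keys.
#'
#' @return Character vector of 48 five-character keys.
#' @export
#' @examples
#' enumerate_strata()[1:4]
enumerate_strata <- function() {
  g <- expand.grid(smoking = 0:2, pa = 0:1, alcohol = 0:1, fv = 0:1,
                   sleep = 0:1, KEEP.OUT.ATTRS = FALSE)
  keys <- sprintf("%d%d%d%d%d", g$sleep, g$fv, g$alcohol, g$pa, g$smoking)
  sort(keys)
}

#' Encode behaviour codes as a stratum key
#'
#' @param coded A `data.frame` (or list) with columns/elements `sleep_meets`,
#'   `fv_meets`, `alcohol_meets`, `pa_meets` (each 0/1) and `smoking_code`
#'   (0 = previous, 1 = current, 2 = never). Vectorised over rows.
#' @return Character vector of 5-digit stratum keys.
#' @export
#' @examples
#' encode_stratum(data.frame(sleep_meets = 0, fv_meets = 1, alcohol_meets = 1,
#'                           pa_meets = 1, smoking_code = 2))  # "01112"
encode_stratum <- function(coded) {
  need <- c("sleep_meets", "fv_meets", "alcohol_meets", "pa_meets",
            "smoking_code")
  missing_cols <- setdiff(need, names(coded))
  if (length(missing_cols))
    stop_maihda("missing behaviour codes: ", paste(missing_cols, collapse = ", "))
  vals <- lapply(need, function(nm) coded[[nm]])
  for (i in seq_along(need)) {
    v <- vals[[i]]
    if (anyNA(v))
      stop_maihda("cannot encode stratum: missing code for ",
                  BEHAVIOUR_LABELS[[c(BEHAVIOURS[1:4], "smoking")[i]]])
    ok <- if (i < 5) v %in% 0:1 else v %in% 0:2
    if (!all(ok))
      stop_maihda("invalid ", need[i], " value: ", v[!ok][1])
  }
  sprintf("%d%d%d%d%d", vals[[1]], vals[[2]], vals[[3]], vals[[4]], vals[[5]])
}

#' Decode a stratum key into behaviour codes and labels
#'
#' @param key A single 5-character stratum key.
#' @return A list with integer codes (`sleep_meets`, `fv_meets`,
#'   `alcohol_meets`, `pa_meets`, `smoking_code`) and human-readable `labels`.
#' @export
#' @examples
#' decode_stratum("01112")
decode_stratum <- function(key) {
  validate_stratum_key(key)
  d <- as.integer(strsplit(key, "")[[1]])
  meets <- function(x) if (x == 1L) "meets" else "not-meets"
  list(
    sleep_meets = d[1], fv_meets = d[2], alcohol_meets = d[3],
    pa_meets = d[4], smoking_code = d[5],
    labels = c(
      sleep = meets(d[1]), fv = meets(d[2]), alcohol = meets(d[3]),
      pa = meets(d[4]),
      smoking = names(SMOKING_CODES)[match(d[5], SMOKING_CODES)]
    )
  )
}

validate_stratum_key <- function(key) {
  if (!is.character(key) || length(key) != 1L || is.na(key))
    stop_maihda("stratum key must be a single character string")
  if (nchar(key) != 5L)
    stop_maihda("invalid stratum key '", key, "': must have 5 digits")
  d <- suppressWarnings(as.integer(strsplit(key, "")[[1]]))
  if (anyNA(d) || any(d[1:4] > 1L) || d[5] > 2L || any(d < 0L))
    stop_maihda("invalid stratum key '", key,
                "': digits 1-4 must be 0/1, digit 5 must be 0/1/2")
  invisible(key)
}

#' Assign analysis-set records to strata
#'
#' Builds the stratum index for an exclusion-applied, fully coded analysis
#' set. All 48 keys are retained, including empty ones (n = 0): predictions
#' for empty strata use the fixed part only.
#'
#' @param coded A coded analysis set (see [recode_behaviours()]) with no
#'   missing behaviour codes.
#' @return An object of class `stratum_index`: a `data.frame` with columns
#'   `stratum` (all 48 keys) and `n`, plus attributes `assignment` (factor of
#'   per-record keys over all 48 levels) and `members` (list of row indices).
#' @export
assign_strata <- function(coded) {
  keys <- encode_stratum(coded)
  lev <- enumerate_strata()
  f <- factor(keys, levels = lev)
  n <- as.integer(table(f))
  idx <- data.frame(stratum = lev, n = n, stringsAsFactors = FALSE)
  attr(idx, "assignment") <- f
  attr(idx, "members") <- split(seq_along(f), f)
  class(idx) <- c("stratum_index", "data.frame")
  idx
}

#' @export
print.stratum_index <- function(x, ...) {
  cat("Stratum index: ", sum(x$n), " records in ", sum(x$n > 0),
      " of 48 strata\n", sep = "")
  invisible(x)
}
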