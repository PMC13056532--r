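# Internal numerical helpers.

# log(sum(exp(x))) along rows of a matrix, guarded against overflow.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# log(1 + exp(x)) without overflow for large x.
log1pexp <- function(x) {
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  mid <- x > 18 & x < 33.3
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_maihda <- function(..., class = "maihda_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
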