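# Internal numeric and RNG helpers.

expit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

#' Derive a deterministic family of replicate seeds
#'
#' All randomness in a scenario flows from a single `base_seed`.  The base
#' seed spawns one seed for the calibration stream plus one per replicate,
#' drawn as a prefix-stable stream: the first `k` seeds are identical no
#' matter how many are requested later.
#'
#' @param base_seed Integer scalar.
#' @param k Number of seeds to derive.
#' @return Integer vector of length `k`, each in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seeds <- function(base_seed, k) {
  stopifnot(is.numeric(base_seed), length(base_seed) == 1L, k >= 1)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old))
  set.seed(as.integer(base_seed))
  sample.int(2147483646L, k)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible()
}

# run expr with the global RNG seeded by `seed`, restoring the caller's
# RNG state afterwards so library code has no side effects on user draws
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old))
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_prob <- function(p) is.numeric(p) && length(p) == 1L && !is.na(p) && p > 0 && p < 1

is_count <- function(n) {
  is.numeric(n) && length(n) == 1L && !is.na(n) && n >= 1 && n == floor(n)
}
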