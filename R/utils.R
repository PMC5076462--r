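# Internal validation and seed helpers.

`%||%` <- rlang::`%||%`

assert_scalar_int <- function(x, name, min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x)) {
    rlang::abort(sprintf("`%s` must be a single integer.", name))
  }
  if (!is.null(min) && x < min) {
    rlang::abort(sprintf("`%s` must be >= %s.", name, min))
  }
  as.integer(x)
}

assert_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    rlang::abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  as.numeric(x)
}

#' Derive a reproducible stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed
#' deterministically from the master seed and the stage name, so stages
#' have independent, reproducible random streams. The derivation hashes
#' the stage name into an integer offset (a small polynomial rolling hash
#' over the UTF-8 bytes) and folds it into the master seed modulo
#' `2^31 - 1`.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage name, e.g. `"corpus"` or `"simulate"`.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @examples
#' stage_seed(1, "corpus")
#' stage_seed(1, "items") # differs
#' @export
stage_seed <- function(master_seed, stage) {
  master_seed <- assert_scalar_int(master_seed, "master_seed")
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, keeps results in integer range
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% m
  as.integer((abs(as.numeric(master_seed)) %% m * 7919 + h) %% m)
}

# sample() without the length-1 surprise: always samples from the
# elements of x.
resample <- function(x, size = length(x), ...) {
  x[sample.int(length(x), size = size, ...)]
}

# Run `code` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code, .rng_kind = "Mersenne-Twister")
}
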