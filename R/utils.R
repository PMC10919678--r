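# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Sets the seed, runs `code`, and restores the caller's `.Random.seed`,
#' so library functions never perturb a user's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a base seed and an integer offset
#'
#' Keeps every derived seed in [0, 2^31 - 2]. Distinct offsets give distinct,
#' well-separated streams so that e.g. adding a code to a generator config
#' does not perturb the label draws of earlier codes.
#' @noRd
derive_seed <- function(seed, offset) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + as.numeric(offset) * 7919 + 1) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)

is_prob <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
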