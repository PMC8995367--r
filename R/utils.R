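# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never disturb user RNG.
with_rng_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a stream of child seeds from a master seed, so independent
# sub-simulations stay reproducible and uncorrelated. Kept below 2^31.
derive_seeds <- function(seed, n) {
  with_rng_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
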