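# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-stream seeds derived from one user-facing seed, so that
# independent stages (genotypes, covariates, folds, permutations) never share
# a stream. Kept below 2^31 - 1.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000000L) * 2048L + (as.integer(index) %% 2048L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mdr <- function(...) stop(..., call. = FALSE)
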