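# Internal helpers shared across the package.

# Evaluate `code` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG state.
# seed = NULL means "use the current stream" (still advances it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a parent seed and a stream label,
# keeping the result inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 1297) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(..., call. = FALSE)
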