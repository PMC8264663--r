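# Internal helpers shared across modules.

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# When seed is NULL the expression just uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a per-stage sub-seed from a base seed; keeps results < 2^31 and
# distinct across stage labels so stages can be reproduced independently.
derive_seed <- function(seed, stage) {
  offsets <- c(sampling = 101L, init = 211L, shuffle = 307L, dropout = 401L,
               data = 503L, eval = 601L)
  off <- offsets[[stage]]
  as.integer((as.double(seed) * 69069 + off) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
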