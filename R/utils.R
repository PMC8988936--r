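# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state.  All exported functions that consume randomness take an explicit
# `seed` argument and route through this, so results are reproducible and
# independent of the surrounding session.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic derived seeds (kept < 2^31).
deriveSeed <- function(seed, offset) {
  (as.integer(seed) * 7919L + as.integer(offset)) %% 2147483647L
}

tripleKey <- function(s, p, o) paste(s, p, o, sep = "\r")

isSingleString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
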