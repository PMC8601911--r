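# Reproducible child seed streams: every generator draws from its own
# deterministic stream derived from (master seed, stream label), so modules
# can be re-run in isolation without disturbing each other or the caller's
# RNG state.

#' Derive a child seed from a master seed and a stream label
#'
#' Deterministic 32-bit hash; different labels give effectively independent
#' streams for the Mersenne-Twister generator.
#'
#' @param seed integer master seed.
#' @param label character stream label.
#' @return A positive integer seed below 2^31.
#' @export
child_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(as.character(label))) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h) + 1L
}

# Evaluate `expr` under a local RNG seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
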