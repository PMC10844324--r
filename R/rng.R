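# Hierarchical seeding: one master seed -> per-model / per-observer / per-use
# streams, so any single simulated observer or fit is independently
# reproducible without replaying the whole pipeline.

#' Derive a child seed from a master seed and integer indices
#'
#' Deterministic integer hash (multiplicative congruential over the Mersenne
#' prime 2^31 - 1) used to give every simulated observer, trial block and
#' Monte-Carlo draw its own reproducible RNG stream.
#'
#' @param seed Master seed (integer).
#' @param ... Integer indices identifying the child stream (e.g. model index,
#'   observer index).
#' @return An integer seed in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, 3, 12) == derive_seed(1, 3, 12)
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- abs(as.double(seed)) %% 2147483647
  # one extra mixing step even when no indices are given
  for (i in c(1, idx)) {
    x <- (x * 48271 + (abs(as.double(i)) + 1) * 9349 + 11) %% 2147483647
  }
  as.integer(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL evaluates as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(expr)
}
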