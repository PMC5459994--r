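#' Derive a child seed from a master seed
#'
#' All stochastic generators in the package draw from a single master seed;
#' child streams (one per clone, per replicate, per stage) are derived
#' deterministically with this function, so that any sub-simulation can be
#' reproduced in isolation and a pool of `n` clones uses exactly the same
#' per-clone streams as `n` individual clone simulations.
#'
#' @param seed Integer master seed.
#' @param index Integer stream index (>= 1).
#' @param salt Optional integer to separate different uses of the same index
#'   (e.g. clone state vs. count noise).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(1, 1)
#' derive_seed(1, 1, salt = 1) # a distinct stream
#' @export
derive_seed <- function(seed, index, salt = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, keeps every derived seed a valid R integer
  s <- abs(as.numeric(seed)) %% m
  s <- (s * 69069 + as.numeric(index) * 101 + as.numeric(salt) * 65537 + 1) %% m
  as.integer(if (s == 0) 1 else s)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}
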