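# RNG helpers shared across generators.

# Evaluate `code` under `set.seed(seed)` (when non-NULL), restoring the
# caller's RNG state afterwards so library code never disturbs user
# simulations.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic fan-out of one master seed into independent child seeds,
# one per generator stream: child = (1009*seed + 9973*k) mod (2^31 - 1).
# Keeps every derived seed a valid 32-bit integer.
child_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((1009 * (abs(seed) %% 2147483647) + 9973 * k) %% 2147483647)
}
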