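# Deterministic derivation of per-task seeds from one user seed.
# Keeps all arithmetic exact in doubles (< 2^53) and the result in
# [0, 2^31 - 2], a valid R integer seed.
mixSeed <- function(seed, ...) {
  M <- 2147483647
  h <- (abs(seed) %% M)
  for (k in c(...)) {
    h <- (h * 48271 + (abs(k) %% M) + 1) %% M
    h <- (h * 16807 + 12345) %% M
  }
  as.integer(h)
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(seed)
  expr
}
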