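# Internal helpers: deterministic seed derivation and RNG scoping.

# Derive a 31-bit seed from a global seed plus arbitrary components
# (integers or strings).  Deterministic, order-sensitive; used so that
# every scan cell / shuffle gets an independent, reproducible stream.
deriveSeed <- function(seed, ...) {
  parts <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p)) %% 2147483647
    for (v in as.numeric(p)) {
      h <- (h * 69069 + (v %% 2147483647) + 12345) %% 2147483647
    }
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
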