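# internal helpers shared across modules

.EPS <- 1e-12

# Run expr under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs the
# user's stream.
withSeed <- function(seed, expr) {
  seed <- as.integer(seed)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# seeds derived from a base seed, kept inside 32-bit integer range
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.assertFinite <- function(m, what) {
  if (any(!is.finite(m))) stop(what, " contains non-finite values")
}

.asAnnotationInput <- function(X) {
  if (is(X, "AnnotationMatrix")) X@X else as.matrix(X)
}
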