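# Internal helpers: seeded RNG scoping and small argument checks.

# Evaluate `expr` under a fixed Mersenne-Twister seed, restoring the caller's
# RNG state afterwards so library calls never perturb user-level randomness.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  }
  force(expr)
}

# Derive a bounded sub-seed from a base seed and a stream index; keeps every
# derived seed inside the 32-bit integer range R requires.
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647L)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

checkPositiveScalar <- function(x, name) {
  stopIfNot(is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0,
            sprintf("'%s' must be a positive finite scalar", name))
}

checkCountScalar <- function(x, name, min = 1L) {
  stopIfNot(is.numeric(x) && length(x) == 1L && is.finite(x) &&
              x >= min && x == floor(x),
            sprintf("'%s' must be an integer >= %d", name, min))
}

asMatrixDense <- function(x) {
  if (methods::is(x, "Matrix")) as.matrix(x) else x
}
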