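# Run code under a temporary RNG seed, restoring the caller's random state.
# All randomness in the package flows through explicit seeds via this helper.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Integer ceiling with a tolerance against floating-point noise, so that
# e.g. ceil(x / s_c) does not round 2.0000000000000004 up to 3.
ceil_tol <- function(x, tol = 1e-9) {
  as.integer(ceiling(x - tol))
}
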