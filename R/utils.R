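# Internal helpers shared across modules.

# Two-sided normal p-value from an estimate and its SE.
p_from_z <- function(z) 2 * pnorm(-abs(z))

# Evaluate code under a local RNG state, restoring .Random.seed afterwards.
# Equivalent to withr::with_seed but kept internal so Imports stay lean.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and an index, staying inside the
# 32-bit signed integer range R requires.
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 1103L + 7919 * i) %% 2147483647)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower && x < upper else x >= lower && x <= upper)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number in %s%s, %s%s.",
                  name, if (strict) "(" else "[", lower, upper,
                  if (strict) ")" else "]"))
  }
  invisible(x)
}

`%||%` <- rlang::`%||%`
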