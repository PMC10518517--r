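# Internal helpers shared across the package.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministically derive `k` child seeds (< 2^31) from one master seed, so
# that independent stochastic stages never share an RNG stream.
derive_seeds <- function(seed, k) {
  if (is.null(seed)) {
    return(rep(list(NULL), k))
  }
  as.list(with_seed(seed, sample.int(.Machine$integer.max - 1L, k)))
}

# Two-sided normal p-value for an estimate/SE pair.
z_pvalue <- function(estimate, se) {
  2 * pnorm(-abs(estimate / se))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > lower && x < upper else x >= lower && x <= upper)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single finite number in %s%s, %s%s.",
      name, if (open) "(" else "[", format(lower), format(upper),
      if (open) ")" else "]"
    ))
  }
  invisible(x)
}
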