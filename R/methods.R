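# broom-style methods for fitted MR estimates.

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf(
    "<mr_result> %s (J = %d): theta = %.4g (SE %.3g), 95%% CI [%.4g, %.4g], p = %.3g\n",
    x$method, x$n_snps, x$theta, x$se, x$ci_low, x$ci_high, x$p_value
  ))
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  intercept = %.4g (SE %.3g), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se,
                x$egger_intercept_p))
  }
  if (is.finite(x$q_statistic %||% NA_real_)) {
    cat(sprintf("  Q = %.4g on %d df (p = %.3g), I^2 = %.3g\n",
                x$q_statistic, x$q_df, x$q_p, x$i_squared))
  }
  invisible(x)
}

#' Tidy a fitted MR estimate
#'
#' One row per fit with the causal estimate on the analysis (beta) scale and
#' its exponentiated odds-ratio form, which is the reporting scale when the
#' outcome is a binary disease on log odds.
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `n_snps`, `theta`, `se`,
#'   `ci_low`, `ci_high`, `p_value`, `or`, `or_ci_low`, `or_ci_high`, and
#'   Egger intercept columns (`NA` for other methods).
#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, ...) {
  tibble(
    method = x$method,
    n_snps = x$n_snps,
    theta = x$theta,
    se = x$se,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    p_value = x$p_value,
    or = exp(x$theta),
    or_ci_low = exp(x$ci_low),
    or_ci_high = exp(x$ci_high),
    egger_intercept = x$egger_intercept %||% NA_real_,
    egger_intercept_se = x$egger_intercept_se %||% NA_real_,
    egger_intercept_p = x$egger_intercept_p %||% NA_real_
  )
}

#' @rdname tidy.mr_result
#' @method glance mr_result
#' @export
glance.mr_result <- function(x, ...) {
  tibble(
    method = x$method,
    n_snps = x$n_snps,
    q_statistic = x$q_statistic,
    q_df = x$q_df,
    q_p = x$q_p,
    i_squared = x$i_squared,
    dispersion = x$dispersion
  )
}
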