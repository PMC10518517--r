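# ggplot2 views of the analysis: scatter with fitted slopes, per-method
# forest, leave-one-out, and funnel.

#' Scatter plot of outcome against exposure effects with fitted slopes
#'
#' @param run An `mr_direction` (or an `mr_harmonized` set).
#' @return A ggplot.
#' @export
plot_mr_scatter <- function(run) {
  if (inherits(run, "mr_direction")) {
    h <- run$harmonized
    fits <- purrr::map_dfr(run$estimates, function(e) {
      tibble(method = e$method, slope = e$theta,
             intercept = e$egger_intercept %||% 0)
    })
  } else {
    h <- run
    fits <- tibble(method = "ivw_mre", slope = mr_ivw(h)$theta,
                   intercept = 0)
  }
  ggplot2::ggplot(as_tibble(h), ggplot2::aes(x = .data$gamma,
                                             y = .data$Gamma)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$Gamma - .data$se_Gamma,
                                        ymax = .data$Gamma + .data$se_Gamma),
                           linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$gamma - .data$se_gamma,
                                         xmax = .data$gamma + .data$se_gamma),
                            linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_abline(
      data = fits,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$method)
    ) +
    ggplot2::labs(x = "variant-exposure effect", y = "variant-outcome effect",
                  colour = "method") +
    ggplot2::theme_minimal()
}

#' Forest plot of per-method causal estimates
#'
#' @param results Tidy results tibble (from an `mr_direction` or
#'   [tidy.mr_result()] rows).
#' @param exponentiate Show odds ratios instead of betas?
#' @return A ggplot.
#' @export
plot_mr_forest <- function(results, exponentiate = FALSE) {
  if (inherits(results, "mr_direction")) results <- results$results
  d <- as_tibble(results)
  if (exponentiate) {
    d <- d %>% mutate(est = .data$or, lo = .data$or_ci_low,
                      hi = .data$or_ci_high)
    ref <- 1
  } else {
    d <- d %>% mutate(est = .data$theta, lo = .data$ci_low,
                      hi = .data$ci_high)
    ref <- 0
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$est, y = .data$method)) +
    ggplot2::geom_vline(xintercept = ref, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = if (exponentiate) "odds ratio (95% CI)"
                      else "causal estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Leave-one-out plot
#'
#' @param loo An `mr_loo` tibble from [mr_leave_one_out()].
#' @return A ggplot.
#' @export
plot_mr_loo <- function(loo) {
  full <- attr(loo, "full")
  ggplot2::ggplot(as_tibble(loo),
                  ggplot2::aes(x = .data$theta,
                               y = .data$excluded_variant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_vline(xintercept = full$theta, colour = "steelblue") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "IVW estimate omitting one variant", y = NULL) +
    ggplot2::theme_minimal()
}

#' Funnel plot
#'
#' @param funnel An `mr_funnel` tibble from [mr_funnel_data()].
#' @param center Optional vertical reference (e.g. the IVW estimate).
#' @return A ggplot.
#' @export
plot_mr_funnel <- function(funnel, center = NULL) {
  p <- ggplot2::ggplot(as_tibble(funnel),
                       ggplot2::aes(x = .data$theta, y = .data$precision)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "per-variant Wald ratio", y = "precision (1/SE)") +
    ggplot2::theme_minimal()
  if (!is.null(center)) {
    p <- p + ggplot2::geom_vline(xintercept = center, linetype = 2,
                                 colour = "grey50")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_mr_scatter
#' @param object An `mr_direction`.
#' @param ... Unused.
#' @method autoplot mr_direction
#' @export
autoplot.mr_direction <- function(object, ...) {
  plot_mr_scatter(object)
}

#' @rdname plot_mr_loo
#' @param object An `mr_loo`.
#' @param ... Unused.
#' @method autoplot mr_loo
#' @export
autoplot.mr_loo <- function(object, ...) {
  plot_mr_loo(object)
}

#' @rdname plot_mr_funnel
#' @param object An `mr_funnel`.
#' @param ... Unused.
#' @method autoplot mr_funnel
#' @export
autoplot.mr_funnel <- function(object, ...) {
  plot_mr_funnel(object)
}
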