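# Causal estimators for two-sample MR on harmonized per-variant effects
# (gamma on the exposure, Gamma on the outcome): Wald ratio, IVW with
# multiplicative random effects, MR-Egger, weighted median, weighted mode,
# plus Cochran's Q / I^2 heterogeneity, leave-one-out, and funnel data.

new_mr_result <- function(method, theta, se, n_snps, p_value = NULL,
                          ci = NULL, df = NULL, q_statistic = NA_real_,
                          q_df = NA_real_, q_p = NA_real_,
                          i_squared = NA_real_, dispersion = NA_real_,
                          egger_intercept = NULL, extra = list()) {
  if (is.null(ci)) {
    crit <- if (is.null(df)) qnorm(0.975) else qt(0.975, df)
    ci <- theta + c(-1, 1) * crit * se
  }
  if (is.null(p_value)) {
    p_value <- if (is.null(df)) z_pvalue(theta, se)
               else 2 * pt(-abs(theta / se), df)
  }
  structure(
    c(list(
      method = method, theta = theta, se = se,
      ci_low = ci[1], ci_high = ci[2], p_value = p_value, n_snps = n_snps,
      q_statistic = q_statistic, q_df = q_df, q_p = q_p,
      i_squared = i_squared, dispersion = dispersion,
      egger_intercept = egger_intercept
    ), extra),
    class = "mr_result"
  )
}

harmonized_columns <- function(data) {
  need <- c("gamma", "se_gamma", "Gamma", "se_Gamma")
  if (!all(need %in% names(data))) {
    abort("Need a harmonized set with columns gamma, se_gamma, Gamma, se_Gamma.")
  }
  as_tibble(data)[, intersect(c("variant_id", need), names(data))]
}

# Per-variant Wald ratios and their first-order (optionally second-order)
# delta-method variances.
ratio_estimates <- function(data, second_order = FALSE) {
  d <- harmonized_columns(data)
  if (any(d$gamma == 0)) abort("gamma = 0 gives an undefined Wald ratio.")
  theta <- d$Gamma / d$gamma
  v <- d$se_Gamma^2 / d$gamma^2
  if (second_order) {
    v <- v + d$Gamma^2 * d$se_gamma^2 / d$gamma^4
  }
  ids <- if ("variant_id" %in% names(d)) d$variant_id
         else as.character(seq_len(nrow(d)))
  tibble(variant_id = ids, theta = theta, variance = v, weight = 1 / v)
}

#' Wald ratio estimate from a single variant
#'
#' The per-variant causal estimate \eqn{\hat\theta = \Gamma / \gamma} with
#' first-order delta-method standard error
#' \eqn{\sigma_\Gamma / |\gamma|} (a second-order term adding the
#' contribution of the exposure SE is available via `second_order`).
#'
#' @param gamma,se_gamma Variant-exposure effect and its SE.
#' @param Gamma,se_Gamma Variant-outcome effect and its SE.
#' @param second_order Add the second-order delta-method variance term?
#' @return An `mr_result`.
#' @export
mr_wald_ratio <- function(gamma, se_gamma, Gamma, se_Gamma,
                          second_order = FALSE) {
  if (gamma == 0) abort("gamma = 0: the Wald ratio is undefined.")
  r <- ratio_estimates(
    tibble(gamma = gamma, se_gamma = se_gamma, Gamma = Gamma,
           se_Gamma = se_Gamma),
    second_order = second_order
  )
  new_mr_result("wald", r$theta, sqrt(r$variance), n_snps = 1L)
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines per-variant Wald ratios by inverse-variance weighting,
#' equivalently a zero-intercept weighted regression of the outcome effects
#' \eqn{\Gamma_j} on the exposure effects \eqn{\gamma_j} with weights
#' \eqn{w_j = 1/\sigma_{\Gamma j}^2}:
#' \deqn{\hat\theta = \sum_j w_j \gamma_j \Gamma_j / \sum_j w_j \gamma_j^2.}
#' With multiplicative random effects (the default) the fixed-effect SE is
#' inflated by \eqn{\sqrt{\max(1, Q/(J-1))}} so heterogeneity widens, and
#' never narrows, the interval. Cochran's Q and \eqn{I^2} are attached.
#' A single-variant set falls back to the Wald ratio with a message.
#'
#' @param data An [harmonize()]d set, or any data frame with columns
#'   `gamma`, `se_gamma`, `Gamma`, `se_Gamma`.
#' @param random_effects Use the multiplicative random-effects SE
#'   (default `TRUE`); `FALSE` gives the fixed-effect SE.
#' @return An `mr_result` with fields `theta`, `se`, `ci_low`, `ci_high`,
#'   `p_value`, `n_snps`, `q_statistic`, `i_squared`, `dispersion`.
#' @export
mr_ivw <- function(data, random_effects = TRUE) {
  d <- harmonized_columns(data)
  J <- nrow(d)
  if (J == 0) abort("Empty instrument set.")
  if (J == 1) {
    inform("Single instrument: IVW falls back to the Wald ratio.")
    return(mr_wald_ratio(d$gamma, d$se_gamma, d$Gamma, d$se_Gamma))
  }
  w <- 1 / d$se_Gamma^2
  s_gg <- sum(w * d$gamma^2)
  theta <- sum(w * d$gamma * d$Gamma) / s_gg
  se_fixed <- 1 / sqrt(s_gg)
  q <- sum(w * (d$Gamma - theta * d$gamma)^2)
  df <- J - 1
  dispersion <- max(1, q / df)
  se <- if (random_effects) se_fixed * sqrt(dispersion) else se_fixed
  i2 <- if (q > 0) max(0, (q - df) / q) else 0
  new_mr_result(
    if (random_effects) "ivw_mre" else "ivw_fixed",
    theta, se, n_snps = J,
    q_statistic = q, q_df = df, q_p = pchisq(q, df, lower.tail = FALSE),
    i_squared = i2, dispersion = dispersion
  )
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects with
#' a free intercept and weights \eqn{1/\sigma_{\Gamma j}^2}, after orienting
#' every variant so its exposure effect is positive. The slope estimates the
#' causal effect under the InSIDE assumption; a nonzero intercept indicates
#' directional horizontal pleiotropy biasing IVW. Standard errors are
#' inflated by \eqn{\sqrt{\max(1, \hat\sigma^2)}} (residual overdispersion
#' floored at 1) and inference uses the t distribution with J - 2 degrees of
#' freedom. Requires at least three instruments.
#'
#' @inheritParams mr_ivw
#' @return An `mr_result` carrying `egger_intercept`, `egger_intercept_se`,
#'   and `egger_intercept_p` alongside the slope estimate.
#' @export
mr_egger <- function(data) {
  d <- harmonized_columns(data)
  J <- nrow(d)
  if (J < 3) abort("MR-Egger needs at least 3 instruments.")
  flip <- sign(d$gamma)
  flip[flip == 0] <- 1
  g <- d$gamma * flip
  G <- d$Gamma * flip
  w <- 1 / d$se_Gamma^2

  sw <- sum(w); swx <- sum(w * g); swy <- sum(w * G)
  swxx <- sum(w * g^2); swxy <- sum(w * g * G)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- G - intercept - slope * g
  df <- J - 2
  s2 <- sum(w * resid^2) / df
  infl <- max(1, s2)
  se_slope <- sqrt(infl * sw / det)
  se_int <- sqrt(infl * swxx / det)
  p_int <- 2 * pt(-abs(intercept / se_int), df)
  new_mr_result(
    "egger", slope, se_slope, n_snps = J, df = df,
    q_statistic = sum(w * resid^2), q_df = df,
    q_p = pchisq(sum(w * resid^2), df, lower.tail = FALSE),
    dispersion = infl,
    egger_intercept = intercept,
    extra = list(egger_intercept_se = se_int, egger_intercept_p = p_int)
  )
}

# Weighted median of values x with weights w by interpolation of the
# standardized cumulative weight at 1/2.
weighted_median_value <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(x[1])
  J <- length(x)
  if (s[J] < 0.5) return(x[J])
  k <- max(which(s < 0.5))
  x[k] + (x[k + 1] - x[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

# Parametric bootstrap SE: redraw (gamma, Gamma) from their reported normal
# sampling distributions and recompute `statistic(theta_j, w_j)` on the
# per-variant ratios and inverse-variance weights.
boot_se <- function(d, n_boot, seed, second_order, statistic) {
  J <- nrow(d)
  with_seed(seed, {
    ests <- vapply(seq_len(n_boot), function(b) {
      g <- rnorm(J, d$gamma, d$se_gamma)
      G <- rnorm(J, d$Gamma, d$se_Gamma)
      v <- d$se_Gamma^2 / g^2
      if (second_order) v <- v + G^2 * d$se_gamma^2 / g^4
      statistic(G / g, 1 / v)
    }, numeric(1))
    sd(ests)
  })
}

#' Weighted-median causal estimate
#'
#' Orders the per-variant Wald ratios and takes the inverse-variance-weighted
#' median by interpolating the standardized cumulative weights at one half.
#' Consistent when at least half the total instrument weight comes from valid
#' instruments. The SE comes from a parametric bootstrap that redraws every
#' \eqn{\gamma_j} and \eqn{\Gamma_j} from normal distributions with their
#' reported SEs.
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed Seed for the bootstrap; the result is reproducible given
#'   (`seed`, `n_boot`).
#' @param second_order Use second-order delta-method ratio variances for the
#'   weights?
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = NULL,
                               second_order = FALSE) {
  d <- harmonized_columns(data)
  if (nrow(d) < 3) abort("Weighted median needs at least 3 instruments.")
  r <- ratio_estimates(d, second_order)
  est <- weighted_median_value(r$theta, r$weight)
  se <- boot_se(d, n_boot, seed, second_order, weighted_median_value)
  if (!is.finite(se) || se <= 0) se <- .Machine$double.eps
  new_mr_result("weighted_median", est, se, n_snps = nrow(d))
}

# Mode of a weighted normal-kernel density over the ratio estimates,
# maximized on a 512-point grid spanning the data range +/- 3 bandwidths.
mode_value <- function(theta, w, phi) {
  if (length(unique(theta)) == 1) return(theta[1])
  m <- sum(w * theta) / sum(w)
  sd_w <- sqrt(sum(w * (theta - m)^2) / sum(w))
  med_w <- weighted_median_value(theta, w)
  mad_w <- weighted_median_value(abs(theta - med_w), w)
  h <- phi * 0.9 * min(sd_w, mad_w / 0.6745) * length(theta)^(-1 / 5)
  if (!is.finite(h) || h <= 0) {
    # Degenerate spread (e.g. weighted MAD = 0): fall back to the weighted
    # median of the tight cluster.
    return(med_w)
  }
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = 512)
  dens <- vapply(grid, function(x) sum(w * dnorm((x - theta) / h)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Weighted-mode causal estimate
#'
#' Forms the inverse-variance-weighted kernel density of the per-variant
#' Wald ratios (normal kernel; modified Silverman bandwidth
#' \eqn{h = \phi \cdot 0.9 \cdot \min(sd_w, mad_w/0.6745) \cdot J^{-1/5}})
#' and returns its mode, located on a 512-point grid spanning the ratios
#' plus/minus three bandwidths. Consistent when the largest cluster of
#' similar ratios comes from valid instruments. SE by parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param phi Bandwidth multiplier (default 1).
#' @return An `mr_result`.
#' @export
mr_weighted_mode <- function(data, phi = 1, n_boot = 1000, seed = NULL,
                             second_order = FALSE) {
  d <- harmonized_columns(data)
  if (nrow(d) < 3) abort("Weighted mode needs at least 3 instruments.")
  r <- ratio_estimates(d, second_order)
  est <- mode_value(r$theta, r$weight, phi)
  se <- boot_se(d, n_boot, seed, second_order,
                function(theta, w) mode_value(theta, w, phi))
  if (!is.finite(se) || se <= 0) se <- .Machine$double.eps
  new_mr_result("weighted_mode", est, se, n_snps = nrow(d))
}

#' Cochran's Q heterogeneity test across Wald ratios
#'
#' \deqn{Q = \sum_j w_j (\hat\theta_j - \hat\theta_{IVW})^2}
#' with first-order ratio weights \eqn{w_j = \gamma_j^2/\sigma_{\Gamma j}^2};
#' the p-value is the upper chi-square tail on J - 1 degrees of freedom and
#' \eqn{I^2 = \max(0, (Q - df)/Q)} expresses the excess heterogeneity as a
#' proportion.
#'
#' @inheritParams mr_ivw
#' @param second_order Use second-order ratio variances?
#' @return One-row tibble: `q_statistic`, `df`, `p_value`, `i_squared`.
#' @export
mr_cochran_q <- function(data, second_order = FALSE) {
  r <- ratio_estimates(data, second_order)
  J <- nrow(r)
  if (J < 2) abort("Cochran's Q needs at least 2 instruments.")
  theta_ivw <- sum(r$weight * r$theta) / sum(r$weight)
  q <- sum(r$weight * (r$theta - theta_ivw)^2)
  df <- J - 1
  tibble(
    q_statistic = q,
    df = df,
    p_value = pchisq(q, df, lower.tail = FALSE),
    i_squared = if (q > 0) max(0, (q - df) / q) else 0
  )
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW (multiplicative random effects) causal effect J
#' times, omitting one variant each time. The attribute `all_same_side` is
#' `TRUE` when every leave-one-out confidence interval excludes zero on the
#' same side as the full estimate.
#'
#' @inheritParams mr_ivw
#' @return A tibble of class `mr_loo`: `excluded_variant`, `theta`, `se`,
#'   `ci_low`, `ci_high`, `p_value`; attributes `full` (the full-set
#'   `mr_result`) and `all_same_side`.
#' @export
mr_leave_one_out <- function(data) {
  d <- harmonized_columns(data)
  J <- nrow(d)
  if (J < 3) abort("Leave-one-out needs at least 3 instruments.")
  full <- mr_ivw(d)
  ids <- if ("variant_id" %in% names(d)) d$variant_id
         else as.character(seq_len(J))
  rows <- purrr::map_dfr(seq_len(J), function(j) {
    fit <- mr_ivw(d[-j, ])
    tibble(
      excluded_variant = ids[j],
      theta = fit$theta, se = fit$se,
      ci_low = fit$ci_low, ci_high = fit$ci_high, p_value = fit$p_value
    )
  })
  side <- sign(full$theta)
  all_same_side <- all(if (side >= 0) rows$ci_low > 0 else rows$ci_high < 0)
  structure(rows, class = c("mr_loo", class(tibble())),
            full = full, all_same_side = all_same_side)
}

#' Funnel-plot data
#'
#' Per-variant Wald ratios against their precisions, plus a standardized
#' signed-rank symmetry score of the ratios about the IVW estimate
#' (approximately zero for a symmetric funnel). With a single variant the
#' score is undefined and flagged `NA`.
#'
#' @inheritParams mr_cochran_q
#' @return A tibble of class `mr_funnel`: `variant_id`, `theta`, `precision`;
#'   attribute `symmetry_score`.
#' @export
mr_funnel_data <- function(data, second_order = FALSE) {
  r <- ratio_estimates(data, second_order)
  out <- tibble(
    variant_id = r$variant_id,
    theta = r$theta,
    precision = 1 / sqrt(r$variance)
  )
  score <- NA_real_
  if (nrow(r) > 1) {
    centered <- r$theta - sum(r$weight * r$theta) / sum(r$weight)
    v <- sum(rank(abs(centered))[centered > 0])
    n <- length(centered)
    score <- (v - n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
  }
  structure(out, class = c("mr_funnel", class(tibble())),
            symmetry_score = score)
}
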