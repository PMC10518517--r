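# Simulation-based pleiotropy residual-sum-of-squares framework:
# global test, per-variant outlier test, and distortion test.

presso_loo_slopes <- function(gamma, Gamma, w) {
  s1 <- sum(w * gamma * Gamma)
  s2 <- sum(w * gamma^2)
  (s1 - w * gamma * Gamma) / (s2 - w * gamma^2)
}

#' Global pleiotropy test by simulated residual sums of squares
#'
#' The observed statistic is the weighted residual sum of squares
#' \deqn{RSS = \sum_j w_j (\Gamma_j - \hat\theta_{(-j)} \gamma_j)^2,}
#' where \eqn{\hat\theta_{(-j)}} is the fixed-effect IVW slope with variant j
#' left out and \eqn{w_j = 1/\sigma_{\Gamma j}^2}. Its null distribution is
#' built by K parametric simulations drawing
#' \eqn{\Gamma_j^* \sim N(\hat\theta_{(-j)}\gamma_j, \sigma_{\Gamma j}^2)} and
#' \eqn{\gamma_j^* \sim N(\gamma_j, \sigma_{\gamma j}^2)} and recomputing the
#' statistic. The empirical p-value uses the add-one correction
#' \eqn{(1 + \#\{RSS^* \ge RSS\})/(K+1)}, so it is never exactly zero.
#' Requires at least 4 instruments so every leave-one-out slope rests on 3.
#'
#' @inheritParams mr_ivw
#' @param n_sim Number of simulated null statistics K (default 1000).
#' @param seed RNG seed; identical (seed, n_sim, input) gives bit-identical
#'   results.
#' @return List with `rss_observed`, `global_p`, `rss_sim` (length-K vector),
#'   `residuals_observed`, `residuals_sim` (K x J matrix), `n_sim`, `seed`.
#' @export
mr_presso_global <- function(data, n_sim = 1000, seed = NULL) {
  d <- harmonized_columns(data)
  J <- nrow(d)
  if (J < 4) abort("The global pleiotropy test needs at least 4 instruments.")
  if (n_sim < 1) abort("n_sim must be at least 1.")
  w <- 1 / d$se_Gamma^2
  loo <- presso_loo_slopes(d$gamma, d$Gamma, w)
  resid_obs <- w * (d$Gamma - loo * d$gamma)^2
  rss_obs <- sum(resid_obs)

  with_seed(seed, {
    G_star <- matrix(rnorm(n_sim * J, mean = rep(loo * d$gamma, each = n_sim),
                           sd = rep(d$se_Gamma, each = n_sim)),
                     nrow = n_sim)
    g_star <- matrix(rnorm(n_sim * J, mean = rep(d$gamma, each = n_sim),
                           sd = rep(d$se_gamma, each = n_sim)),
                     nrow = n_sim)
    wE <- sweep(g_star * G_star, 2, w, `*`)
    wF <- sweep(g_star^2, 2, w, `*`)
    loo_star <- (rowSums(wE) - wE) / (rowSums(wF) - wF)
    resid_star <- sweep((G_star - loo_star * g_star)^2, 2, w, `*`)
    rss_star <- rowSums(resid_star)
    list(
      rss_observed = rss_obs,
      global_p = (1 + sum(rss_star >= rss_obs)) / (n_sim + 1),
      rss_sim = rss_star,
      residuals_observed = setNames(resid_obs, d$variant_id),
      residuals_sim = resid_star,
      n_sim = n_sim,
      seed = seed
    )
  })
}

#' Per-variant outlier test from the global-test simulations
#'
#' Each variant's observed residual contribution is compared against its own
#' simulated null draws; the empirical p-values are Bonferroni-adjusted by J
#' and variants with adjusted p below `alpha` are flagged as outliers.
#'
#' @param global Result of [mr_presso_global()].
#' @param alpha Family-wise outlier significance level (default 0.05).
#' @return Tibble: `variant_id`, `residual`, `p_value`,
#'   `p_value_bonferroni`, `outlier`.
#' @export
mr_presso_outlier <- function(global, alpha = 0.05) {
  resid_obs <- global$residuals_observed
  J <- length(resid_obs)
  K <- global$n_sim
  p <- (1 + colSums(global$residuals_sim >=
                      matrix(resid_obs, nrow = K, ncol = J, byrow = TRUE))) /
    (K + 1)
  tibble(
    variant_id = names(resid_obs),
    residual = unname(resid_obs),
    p_value = p,
    p_value_bonferroni = pmin(1, p * J),
    outlier = pmin(1, p * J) < alpha
  )
}

#' Distortion test for outlier-corrected estimates
#'
#' The observed distortion is the relative change of the IVW estimate after
#' removing the flagged outliers,
#' \eqn{(\hat\theta_{-out} - \hat\theta_{all})/|\hat\theta_{all}|}. Its null
#' distribution comes from removing equally many randomly chosen variants K
#' times; the two-sided empirical p-value compares absolute distortions.
#'
#' @inheritParams mr_ivw
#' @param outliers Character vector of outlier variant ids (non-empty).
#' @inheritParams mr_presso_global
#' @return List with `distortion_observed`, `distortion_p`, `n_sim`, `seed`.
#' @export
mr_presso_distortion <- function(data, outliers, n_sim = 1000, seed = NULL) {
  d <- harmonized_columns(data)
  if (length(outliers) == 0) abort("Distortion test needs a non-empty outlier set.")
  keep <- !(d$variant_id %in% outliers)
  if (sum(keep) < 2) {
    abort("Corrected estimate needs at least 2 non-outlier instruments.")
  }
  theta_all <- mr_ivw(d)$theta
  theta_corr <- mr_ivw(d[keep, ])$theta
  d_obs <- (theta_corr - theta_all) / abs(theta_all)
  k_out <- length(intersect(outliers, d$variant_id))
  with_seed(seed, {
    d_null <- vapply(seq_len(n_sim), function(i) {
      drop <- sample.int(nrow(d), k_out)
      (mr_ivw(d[-drop, ])$theta - theta_all) / abs(theta_all)
    }, numeric(1))
    list(
      distortion_observed = d_obs,
      distortion_p = (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1),
      n_sim = n_sim,
      seed = seed
    )
  })
}

#' Run the full pleiotropy residual-sum-of-squares procedure
#'
#' Global test, per-variant outlier test, the outlier-corrected IVW estimate,
#' and (when outliers are flagged and enough instruments remain) the
#' distortion test.
#'
#' @inheritParams mr_ivw
#' @inheritParams mr_presso_global
#' @param outlier_alpha Family-wise significance level for the outlier test
#'   (default 0.05, Bonferroni-adjusted across instruments).
#' @return An object of class `mr_presso`: list with `rss_observed`,
#'   `global_p`, `per_snp` (outlier-test tibble), `outliers`, `raw_estimate`
#'   and `corrected_estimate` (`mr_result`s; corrected is `NULL` without
#'   outliers), `distortion_p` (`NA` when not run), `n_sim`, `seed`.
#' @export
mr_presso <- function(data, n_sim = 1000, seed = NULL, outlier_alpha = 0.05) {
  d <- harmonized_columns(data)
  seeds <- derive_seeds(seed, 2)
  glob <- mr_presso_global(d, n_sim = n_sim, seed = seeds[[1]])
  per_snp <- mr_presso_outlier(glob, alpha = outlier_alpha)
  outliers <- per_snp$variant_id[per_snp$outlier]
  raw <- mr_ivw(d)
  corrected <- NULL
  distortion_p <- NA_real_
  distortion_observed <- NA_real_
  if (length(outliers) > 0 && nrow(d) - length(outliers) >= 2) {
    corrected <- mr_ivw(d[!(d$variant_id %in% outliers), ])
    dist <- mr_presso_distortion(d, outliers, n_sim = n_sim,
                                 seed = seeds[[2]])
    distortion_p <- dist$distortion_p
    distortion_observed <- dist$distortion_observed
  }
  structure(
    list(
      rss_observed = glob$rss_observed,
      global_p = glob$global_p,
      per_snp = per_snp,
      outliers = outliers,
      raw_estimate = raw,
      corrected_estimate = corrected,
      distortion_observed = distortion_observed,
      distortion_p = distortion_p,
      n_sim = n_sim,
      seed = seed
    ),
    class = "mr_presso"
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf(
    "<mr_presso> RSS = %.4g, global p = %.4g (K = %d)\n",
    x$rss_observed, x$global_p, x$n_sim
  ))
  if (length(x$outliers) > 0) {
    cat(sprintf("  outliers: %s; distortion p = %.4g\n",
                paste(x$outliers, collapse = ", "), x$distortion_p))
  } else {
    cat("  no outliers flagged\n")
  }
  invisible(x)
}

#' @rdname mr_presso
#' @param x An `mr_presso` object.
#' @param ... Unused.
#' @method tidy mr_presso
#' @export
tidy.mr_presso <- function(x, ...) {
  x$per_snp
}

#' @rdname mr_presso
#' @method glance mr_presso
#' @export
glance.mr_presso <- function(x, ...) {
  tibble(
    rss_observed = x$rss_observed,
    global_p = x$global_p,
    n_outliers = length(x$outliers),
    distortion_p = x$distortion_p,
    n_sim = x$n_sim
  )
}
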