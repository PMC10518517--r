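# Orchestration: one causal direction (threshold -> clump -> screens -> weak
# filter -> proxies -> harmonize -> estimators -> diagnostics), the
# bidirectional batch over a panel of factors, Bonferroni correction, and
# report rendering.

#' Analysis configuration
#'
#' Collects every tunable of the pipeline with the defaults used throughout:
#' genome-wide significance 5e-8 with a relaxed 1e-5 fallback when fewer than
#' 3 variants reach it, clumping at r2 < 0.001 within 10 Mb, weak-instrument
#' cutoff F < 10, proxies at r2 > 0.9, 1000 bootstrap and simulation
#' replicates, and significance level 0.05.
#'
#' @param p_threshold `"auto"` (threshold rule decides) or a fixed numeric
#'   threshold.
#' @param strict,relaxed,min_gs_snps Parameters of [choose_p_threshold()].
#' @param clump_r2,clump_window_bp Parameters of [clump_variants()].
#' @param f_min Weak-instrument F cutoff.
#' @param proxy_r2 Minimum r2 for LD proxies.
#' @param screens Named list of screen `gwas_sumstats` for
#'   [screen_instruments()].
#' @param ld An [ld_reference()] or `NULL`.
#' @param pre_clumped Treat candidate lists as already independent?
#' @param n_boot Bootstrap replicates for median/mode SEs.
#' @param presso_n_sim Simulations for the pleiotropy RSS tests.
#' @param mode_phi Bandwidth multiplier of the weighted mode.
#' @param second_order Second-order delta-method ratio variances?
#' @param alpha Significance level.
#' @param bonferroni_m Number of tests for Bonferroni adjustment; `NULL`
#'   defaults to the number of exposure traits in the direction being run.
#' @param seed Master seed; all stochastic stages derive their own seeds
#'   from it.
#' @return A list of class `mr_config`.
#' @export
mr_config <- function(p_threshold = "auto", strict = 5e-8, relaxed = 1e-5,
                      min_gs_snps = 3, clump_r2 = 0.001,
                      clump_window_bp = 1e7, f_min = 10, proxy_r2 = 0.9,
                      screens = list(), ld = NULL, pre_clumped = FALSE,
                      n_boot = 1000, presso_n_sim = 1000, mode_phi = 1,
                      second_order = FALSE, alpha = 0.05,
                      bonferroni_m = NULL, seed = 1L) {
  assert_scalar_number(alpha, "alpha", 0, 1, open = TRUE)
  structure(
    list(
      p_threshold = p_threshold, strict = strict, relaxed = relaxed,
      min_gs_snps = min_gs_snps, clump_r2 = clump_r2,
      clump_window_bp = clump_window_bp, f_min = f_min, proxy_r2 = proxy_r2,
      screens = screens, ld = ld, pre_clumped = pre_clumped,
      n_boot = n_boot, presso_n_sim = presso_n_sim, mode_phi = mode_phi,
      second_order = second_order, alpha = alpha,
      bonferroni_m = bonferroni_m, seed = seed
    ),
    class = "mr_config"
  )
}

not_estimable <- function(exposure_id, outcome_id, stage, exclusions,
                          threshold = NULL) {
  structure(
    list(
      exposure_id = exposure_id, outcome_id = outcome_id,
      status = sprintf("not estimable: %s", stage),
      results = tibble(), exclusions = exclusions, threshold = threshold,
      instruments = tibble(), harmonized = NULL, estimates = list(),
      heterogeneity = NULL, loo = NULL, funnel = NULL, presso = NULL
    ),
    class = "mr_direction"
  )
}

log_removed <- function(exclusions, removed, stage) {
  if (is.null(removed) || nrow(removed) == 0) return(exclusions)
  bind_rows(exclusions,
            tibble(stage = stage, variant_id = removed$variant_id,
                   reason = removed$reason))
}

#' Run one causal direction
#'
#' Executes the full pipeline for an exposure-outcome pair: scale conversion
#' of BOLT-LMM binary traits, p-value threshold choice, LD clumping,
#' confounder/outcome screens, instrument-strength filtering, LD-proxy
#' substitution for variants missing from the outcome, allele harmonization,
#' the five causal estimators, heterogeneity statistics, leave-one-out,
#' funnel data, and the pleiotropy RSS tests. Every exclusion is logged with
#' its stage; a pair whose instrument set empties is reported as not
#' estimable at the stage that emptied it, never as an error.
#'
#' @param exposure,outcome `gwas_sumstats` datasets.
#' @param config An [mr_config()].
#' @return An object of class `mr_direction` with fields `results` (tidy
#'   per-method rows with OR columns), `instruments`, `harmonized`,
#'   `estimates`, `heterogeneity`, `loo`, `funnel`, `presso`, `exclusions`,
#'   `threshold`, `status` (`"ok"` or `"not estimable: <stage>"`).
#' @export
mr_run_direction <- function(exposure, outcome, config = mr_config()) {
  stopifnot(inherits(config, "mr_config"))
  exposure_id <- attr(exposure, "trait_id") %||% "exposure"
  outcome_id <- attr(outcome, "trait_id") %||% "outcome"
  exclusions <- tibble(stage = character(), variant_id = character(),
                       reason = character())

  convert_if_needed <- function(x) {
    meta <- trait_meta(x)
    if (identical(meta$trait_type, "binary") &&
        identical(meta$scale, "linear-boltlmm") &&
        !is.null(meta$case_fraction)) {
      convert_boltlmm_to_logor(x)
    } else {
      x
    }
  }
  exposure <- convert_if_needed(exposure)
  outcome <- convert_if_needed(outcome)
  outcome_meta <- trait_meta(outcome)

  # Threshold choice.
  thr <- if (identical(config$p_threshold, "auto")) {
    choose_p_threshold(exposure, config$strict, config$relaxed,
                       config$min_gs_snps)
  } else {
    list(threshold = as.numeric(config$p_threshold), rule = "fixed",
         n_gs = sum(exposure$p_value < config$strict))
  }

  # Clump.
  clumped <- clump_variants(exposure, thr$threshold, ld = config$ld,
                            clump_r2 = config$clump_r2,
                            clump_window_bp = config$clump_window_bp,
                            pre_clumped = config$pre_clumped)
  exclusions <- log_removed(exclusions, attr(clumped, "removed"), "clump")
  if (nrow(clumped) == 0) {
    return(not_estimable(exposure_id, outcome_id, "threshold/clump",
                         exclusions, thr))
  }

  # Confounder / outcome screens.
  screened <- screen_instruments(clumped, config$screens,
                                 alpha = config$alpha)
  exclusions <- log_removed(exclusions, attr(screened, "removed"), "screen")
  if (nrow(screened) == 0) {
    return(not_estimable(exposure_id, outcome_id, "screen", exclusions, thr))
  }

  # Instrument strength and weak filter.
  strong <- filter_weak_instruments(add_instrument_strength(screened),
                                    config$f_min)
  exclusions <- log_removed(exclusions, attr(strong, "removed"),
                            "weak-filter")
  if (nrow(strong) == 0) {
    return(not_estimable(exposure_id, outcome_id, "weak-filter", exclusions,
                         thr))
  }

  # Proxy substitution for instruments missing from the outcome.
  instruments <- strong
  missing <- setdiff(instruments$variant_id, outcome$variant_id)
  if (length(missing) > 0 && !is.null(config$ld)) {
    prox <- find_proxies(missing, config$ld, outcome,
                         r2_min = config$proxy_r2)
    unproxied <- attr(prox, "unproxied")
    if (length(unproxied) > 0) {
      exclusions <- bind_rows(exclusions, tibble(
        stage = "proxy", variant_id = unproxied,
        reason = "missing in outcome, no proxy"
      ))
    }
    if (nrow(prox) > 0) {
      in_exposure <- prox$proxy_id %in% exposure$variant_id
      if (any(!in_exposure)) {
        exclusions <- bind_rows(exclusions, tibble(
          stage = "proxy", variant_id = prox$variant_id[!in_exposure],
          reason = "proxy not in exposure"
        ))
      }
      exclusions <- bind_rows(exclusions, tibble(
        stage = "proxy", variant_id = prox$variant_id[in_exposure],
        reason = sprintf("substituted by proxy %s (r2 = %.3g)",
                         prox$proxy_id[in_exposure], prox$r2[in_exposure])
      ))
      keep_ids <- setdiff(instruments$variant_id, missing)
      new_ids <- setdiff(prox$proxy_id[in_exposure], keep_ids)
      proxies <- as_tibble(exposure)[
        match(new_ids, exposure$variant_id), , drop = FALSE]
      instruments <- bind_rows(
        instruments %>% filter(.data$variant_id %in% keep_ids),
        if (nrow(proxies) > 0) add_instrument_strength(proxies) else NULL
      )
    } else {
      instruments <- instruments %>%
        filter(!(.data$variant_id %in% missing))
    }
  }
  if (nrow(instruments) == 0) {
    return(not_estimable(exposure_id, outcome_id, "proxy", exclusions, thr))
  }

  # Harmonize.
  harmonized <- tryCatch(
    harmonize(instruments, outcome, exposure_id, outcome_id),
    bidirmr_empty_harmonized = function(cnd) {
      exclusions <<- bind_rows(
        exclusions,
        tibble(stage = "harmonize", variant_id = cnd$exclusions$variant_id,
               reason = cnd$exclusions$reason)
      )
      NULL
    }
  )
  if (is.null(harmonized)) {
    return(not_estimable(exposure_id, outcome_id, "harmonization",
                         exclusions, thr))
  }
  exclusions <- log_removed(exclusions, harmonization_exclusions(harmonized),
                            "harmonize")

  # Estimators and diagnostics.
  J <- nrow(harmonized)
  seeds <- derive_seeds(config$seed, 3)
  estimates <- list(ivw_mre = mr_ivw(harmonized, random_effects = TRUE))
  if (J >= 3) {
    estimates$egger <- mr_egger(harmonized)
    estimates$weighted_median <- mr_weighted_median(
      harmonized, n_boot = config$n_boot, seed = seeds[[1]],
      second_order = config$second_order
    )
    estimates$weighted_mode <- mr_weighted_mode(
      harmonized, phi = config$mode_phi, n_boot = config$n_boot,
      seed = seeds[[2]], second_order = config$second_order
    )
  }
  heterogeneity <- if (J >= 2) {
    mr_cochran_q(harmonized, second_order = config$second_order)
  }
  loo <- if (J >= 3) mr_leave_one_out(harmonized)
  funnel <- mr_funnel_data(harmonized, second_order = config$second_order)
  presso <- if (J >= 4) {
    mr_presso(harmonized, n_sim = config$presso_n_sim, seed = seeds[[3]])
  }

  results <- purrr::map_dfr(estimates, tidy) %>%
    mutate(
      exposure = exposure_id, outcome = outcome_id,
      outcome_binary = identical(outcome_meta$trait_type, "binary"),
      .before = 1
    )

  structure(
    list(
      exposure_id = exposure_id, outcome_id = outcome_id, status = "ok",
      threshold = thr, instruments = as_tibble(instruments),
      harmonized = harmonized, estimates = estimates, results = results,
      heterogeneity = heterogeneity, loo = loo, funnel = funnel,
      presso = presso, exclusions = exclusions
    ),
    class = "mr_direction"
  )
}

#' Run the bidirectional analysis over a panel of factors
#'
#' Forward: each factor as exposure against the disease outcome (odds-ratio
#' scale). Reverse: the disease as exposure against each factor (beta
#' scale); the disease instrument set is selected once and reused, with
#' per-factor proxy substitution and harmonization still applied. A factor
#' failing in one direction still runs in the other. Primary (IVW) p-values
#' are Bonferroni-adjusted within each direction across the factors tested;
#' significance flags use the raw p at `config$alpha`, with the adjusted p
#' reported alongside.
#'
#' @param factors Named list of `gwas_sumstats` exposures.
#' @param disease A `gwas_sumstats` disease dataset.
#' @param config An [mr_config()]; `bonferroni_m` defaults to
#'   `length(factors)`.
#' @return An object of class `mr_bidirectional`: list with `forward` and
#'   `reverse` (named lists of `mr_direction`), and `results`, a combined
#'   tidy tibble with `direction`, `p_bonferroni`, `significant_raw`
#'   columns.
#' @export
mr_run_bidirectional <- function(factors, disease, config = mr_config()) {
  if (is.null(names(factors)) || any(names(factors) == "")) {
    abort("`factors` must be a named list of datasets.")
  }
  m <- config$bonferroni_m %||% length(factors)

  forward <- purrr::map(factors, function(fx) {
    mr_run_direction(fx, disease, config)
  })
  reverse <- purrr::map(factors, function(fx) {
    mr_run_direction(disease, fx, config)
  })

  collect <- function(runs, direction) {
    purrr::imap_dfr(runs, function(run, nm) {
      if (nrow(run$results) == 0) {
        return(tibble(direction = direction, factor = nm,
                      status = run$status))
      }
      run$results %>%
        mutate(direction = direction, factor = nm, status = run$status,
               .before = 1)
    })
  }
  results <- bind_rows(collect(forward, "forward"),
                       collect(reverse, "reverse"))
  if ("p_value" %in% names(results)) {
    results <- results %>%
      mutate(
        p_bonferroni = mr_adjust_pvalues(.data$p_value, m),
        significant_raw = !is.na(.data$p_value) &
          .data$p_value < config$alpha
      )
  }
  structure(
    list(forward = forward, reverse = reverse, results = results,
         bonferroni_m = m, config = config),
    class = "mr_bidirectional"
  )
}

#' Bonferroni adjustment with an explicit test count
#'
#' @param p Vector of raw p-values in (0, 1].
#' @param m Number of tests (>= 1); defaults to `length(p)`.
#' @return `pmin(1, p * m)` via [stats::p.adjust()] when `m >= length(p)`.
#' @export
mr_adjust_pvalues <- function(p, m = length(p)) {
  if (m < 1) abort("m must be at least 1.")
  if (m >= length(p)) {
    p.adjust(p, method = "bonferroni", n = m)
  } else {
    pmin(1, p * m)
  }
}

#' Write the full report of a direction run
#'
#' Writes six files to `out_dir`: `results.tsv`, `exclusions.tsv`,
#' `loo.tsv`, `funnel.tsv`, `presso.tsv`, and `summary.json` (a
#' machine-readable digest embedding the run configuration and seeds, so an
#' identical configuration reproduces every numeric output byte). Stages
#' that did not run (too few instruments) yield header-only files.
#'
#' @param run An `mr_direction`.
#' @param out_dir Output directory, created if needed.
#' @return Character vector of files written, invisibly.
#' @export
mr_render_report <- function(run, out_dir) {
  stopifnot(inherits(run, "mr_direction"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  empty <- list(
    results = tibble(method = character(), theta = numeric(),
                     se = numeric(), p_value = numeric()),
    loo = tibble(excluded_variant = character(), theta = numeric(),
                 se = numeric()),
    funnel = tibble(variant_id = character(), theta = numeric(),
                    precision = numeric()),
    presso = tibble(variant_id = character(), residual = numeric(),
                    p_value = numeric())
  )
  files <- c(
    results = file.path(out_dir, "results.tsv"),
    exclusions = file.path(out_dir, "exclusions.tsv"),
    loo = file.path(out_dir, "loo.tsv"),
    funnel = file.path(out_dir, "funnel.tsv"),
    presso = file.path(out_dir, "presso.tsv"),
    summary = file.path(out_dir, "summary.json")
  )
  readr::write_tsv(if (nrow(run$results) > 0) run$results else empty$results,
                   files[["results"]], progress = FALSE)
  readr::write_tsv(run$exclusions, files[["exclusions"]], progress = FALSE)
  readr::write_tsv(if (!is.null(run$loo)) as_tibble(run$loo) else empty$loo,
                   files[["loo"]], progress = FALSE)
  readr::write_tsv(
    if (!is.null(run$funnel)) as_tibble(run$funnel) else empty$funnel,
    files[["funnel"]], progress = FALSE
  )
  readr::write_tsv(
    if (!is.null(run$presso)) run$presso$per_snp else empty$presso,
    files[["presso"]], progress = FALSE
  )
  summary <- list(
    exposure = run$exposure_id,
    outcome = run$outcome_id,
    status = run$status,
    threshold = run$threshold,
    n_instruments = nrow(run$instruments),
    n_harmonized = if (!is.null(run$harmonized)) nrow(run$harmonized) else 0L,
    heterogeneity = run$heterogeneity,
    presso = if (!is.null(run$presso)) glance(run$presso),
    funnel_symmetry = if (!is.null(run$funnel))
      attr(run$funnel, "symmetry_score")
  )
  jsonlite::write_json(summary, files[["summary"]], auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  invisible(unname(files))
}

#' @export
print.mr_direction <- function(x, ...) {
  cat(sprintf("<mr_direction> %s -> %s [%s]\n", x$exposure_id, x$outcome_id,
              x$status))
  if (!is.null(x$threshold)) {
    cat(sprintf("  threshold %.3g (%s rule, %d genome-wide variants)\n",
                x$threshold$threshold, x$threshold$rule, x$threshold$n_gs))
  }
  if (nrow(x$results) > 0) {
    print(x$results)
  }
  invisible(x)
}

#' @rdname mr_run_direction
#' @param x An `mr_direction` object.
#' @param ... Unused.
#' @method tidy mr_direction
#' @export
tidy.mr_direction <- function(x, ...) {
  x$results
}

#' @rdname mr_run_direction
#' @method glance mr_direction
#' @export
glance.mr_direction <- function(x, ...) {
  tibble(
    exposure = x$exposure_id,
    outcome = x$outcome_id,
    status = x$status,
    p_threshold = x$threshold$threshold %||% NA_real_,
    threshold_rule = x$threshold$rule %||% NA_character_,
    n_instruments = nrow(x$instruments),
    n_harmonized = if (!is.null(x$harmonized)) nrow(x$harmonized) else 0L,
    q_statistic = x$heterogeneity$q_statistic %||% NA_real_,
    q_p = x$heterogeneity$p_value %||% NA_real_,
    i_squared = x$heterogeneity$i_squared %||% NA_real_,
    presso_global_p = if (!is.null(x$presso)) x$presso$global_p
                      else NA_real_
  )
}

#' @rdname mr_run_bidirectional
#' @param x An `mr_bidirectional` object.
#' @param ... Unused.
#' @method tidy mr_bidirectional
#' @export
tidy.mr_bidirectional <- function(x, ...) {
  x$results
}
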