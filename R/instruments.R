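# Instrument selection: p-value thresholding, greedy LD clumping, instrument
# strength (R^2 and F), weak-instrument and confounder/outcome screens, and
# LD-proxy substitution for variants missing from the outcome dataset.

#' Choose the instrument p-value threshold
#'
#' Instruments are taken at genome-wide significance (p < `strict`) when the
#' exposure has at least `min_gs_snps` variants reaching it; otherwise the
#' relaxed threshold is adopted so that under-powered exposures still yield
#' an instrument set.
#'
#' @param data A `gwas_sumstats` (or data frame with `p_value`).
#' @param strict Genome-wide significance threshold (default 5e-8).
#' @param relaxed Fallback threshold (default 1e-5).
#' @param min_gs_snps Minimum genome-wide-significant variants needed to use
#'   the strict threshold (default 3).
#' @return A list with `threshold`, `rule` (`"genome-wide"` or `"relaxed"`),
#'   and `n_gs`, the count of variants below `strict`.
#' @export
choose_p_threshold <- function(data, strict = 5e-8, relaxed = 1e-5,
                               min_gs_snps = 3) {
  if (nrow(data) == 0) abort("Empty dataset: cannot choose a p threshold.")
  n_gs <- sum(data$p_value < strict)
  if (n_gs >= min_gs_snps) {
    list(threshold = strict, rule = "genome-wide", n_gs = n_gs)
  } else {
    list(threshold = relaxed, rule = "relaxed", n_gs = n_gs)
  }
}

#' Greedy LD clumping
#'
#' Candidates below the p threshold are ranked by ascending p (variant id
#' breaks ties, making the result invariant to input row order). The best
#' remaining candidate is kept and every other candidate with
#' r2 >= `clump_r2` within `clump_window_bp` on the same chromosome is
#' removed, until no candidates remain.
#'
#' @param data A `gwas_sumstats` (or data frame with the canonical columns).
#' @param p_threshold Candidate inclusion threshold.
#' @param ld An [ld_reference()], required unless `pre_clumped = TRUE`.
#' @param clump_r2 r2 above which two candidates are dependent
#'   (default 0.001).
#' @param clump_window_bp Window within which LD is enforced (default 10 Mb).
#' @param pre_clumped Set `TRUE` for instrument lists that are already
#'   mutually independent (e.g. published per-variant instrument tables);
#'   candidates are then only thresholded and ordered.
#' @return Tibble of retained candidate rows, p-ascending, with attribute
#'   `"removed"`: a tibble of (`variant_id`, `reason`, `index_variant`).
#' @export
clump_variants <- function(data, p_threshold, ld = NULL, clump_r2 = 0.001,
                           clump_window_bp = 1e7, pre_clumped = FALSE) {
  cand <- as_tibble(data) %>%
    filter(.data$p_value < p_threshold) %>%
    arrange(.data$p_value, .data$variant_id)
  removed <- tibble(variant_id = character(), reason = character(),
                    index_variant = character())
  if (pre_clumped || nrow(cand) <= 1) {
    attr(cand, "removed") <- removed
    return(cand)
  }
  if (is.null(ld)) {
    abort("LD reference required for clumping (or set pre_clumped = TRUE).")
  }
  keep <- integer()
  pool <- seq_len(nrow(cand))
  while (length(pool) > 0) {
    best <- pool[1]
    keep <- c(keep, best)
    pool <- pool[-1]
    if (length(pool) == 0) break
    r2 <- ld_r2(ld, cand$variant_id[best], cand$variant_id[pool])
    near <- cand$chromosome[pool] == cand$chromosome[best] &
      abs(cand$position[pool] - cand$position[best]) <= clump_window_bp
    kill <- r2 >= clump_r2 & near
    if (any(kill)) {
      removed <- bind_rows(removed, tibble(
        variant_id = cand$variant_id[pool[kill]],
        reason = "clumped",
        index_variant = cand$variant_id[best]
      ))
      pool <- pool[!kill]
    }
  }
  out <- cand[sort(keep), ] %>% arrange(.data$p_value, .data$variant_id)
  attr(out, "removed") <- removed
  out
}

#' Variance in the trait explained by a variant
#'
#' For an effect-allele frequency EAF and per-allele effect beta on a
#' standardized trait, the explained variance is
#' \deqn{R^2 = 2 \cdot EAF \cdot (1 - EAF) \cdot \beta^2.}
#' Values exceeding 1 (possible when beta is not standardized) are clipped
#' just below 1 with a warning.
#'
#' @param eaf Effect-allele frequency in (0, 1); vectorized.
#' @param beta Per-allele effect; vectorized.
#' @return Numeric vector of R-squared values.
#' @export
compute_r_squared <- function(eaf, beta) {
  if (any(!is.finite(eaf) | eaf <= 0 | eaf >= 1)) {
    abort("eaf must lie strictly in (0, 1).")
  }
  r2 <- 2 * eaf * (1 - eaf) * beta^2
  if (any(r2 > 1)) {
    warn("R^2 above 1 clipped; check that beta is on a standardized scale.")
    r2 <- pmin(r2, 1 - 1e-12)
  }
  r2
}

#' Instrument-strength F statistic
#'
#' \deqn{F = R^2 (N - 2) / (1 - R^2)} where N is the sample size of the GWAS
#' that estimated the variant-trait effect. F below 10 conventionally marks a
#' weak instrument.
#'
#' @param r_squared Explained-variance proportion in [0, 1); vectorized.
#' @param n GWAS sample size (> 2); vectorized.
#' @return Numeric vector of F statistics.
#' @export
compute_f_statistic <- function(r_squared, n) {
  if (any(!is.finite(r_squared) | r_squared < 0 | r_squared >= 1)) {
    abort("r_squared must lie in [0, 1).")
  }
  if (any(n <= 2)) abort("n must exceed 2.")
  r_squared * (n - 2) / (1 - r_squared)
}

#' Attach R-squared and F columns to an instrument table
#'
#' @param data Data frame with `eaf`, `beta`, `n`.
#' @return `data` with `r_squared` and `f_statistic` columns added.
#' @export
add_instrument_strength <- function(data) {
  data %>% mutate(
    r_squared = compute_r_squared(.data$eaf, .data$beta),
    f_statistic = compute_f_statistic(.data$r_squared, .data$n)
  )
}

#' Drop weak instruments
#'
#' Retains variants with F >= `f_min` (the conventional cutoff excludes
#' F < 10; F exactly 10 is retained).
#'
#' @param data Instrument table with an `f_statistic` column (see
#'   [add_instrument_strength()]).
#' @param f_min Minimum F statistic (default 10).
#' @return Filtered tibble with attribute `"removed"` logging exclusions with
#'   reason `"weak"`.
#' @export
filter_weak_instruments <- function(data, f_min = 10) {
  weak <- data$f_statistic < f_min
  out <- as_tibble(data)[!weak, ]
  attr(out, "removed") <- tibble(variant_id = data$variant_id[weak],
                                 reason = "weak")
  out
}

#' Screen instruments against confounder and outcome associations
#'
#' For each screen dataset (e.g. BMI, age at recruitment, or the outcome
#' itself), instruments present in the screen are tested at the Bonferroni
#' threshold `alpha` divided by the number of instruments testable in that
#' screen; any instrument associated below the threshold is removed.
#' Instruments absent from a screen are retained and logged as not testable.
#'
#' @param data Instrument table (rows of the exposure dataset).
#' @param screens Named list of `gwas_sumstats` screen datasets. A screen
#'   named `"outcome"` logs exclusions as `"outcome-associated"`; any other
#'   name as `"confounder:<name>"`.
#' @param alpha Family-wise error rate before division (default 0.05).
#' @return Filtered tibble; attribute `"removed"` logs exclusions and
#'   attribute `"notes"` logs untestable instruments.
#' @export
screen_instruments <- function(data, screens, alpha = 0.05) {
  out <- as_tibble(data)
  removed <- tibble(variant_id = character(), reason = character())
  notes <- tibble(variant_id = character(), note = character())
  for (name in names(screens)) {
    scr <- screens[[name]]
    if (is.null(scr) || nrow(scr) == 0) {
      warn(sprintf("Screen '%s' is empty; skipped.", name))
      next
    }
    hit <- match(out$variant_id, scr$variant_id)
    testable <- !is.na(hit)
    if (any(!testable)) {
      notes <- bind_rows(notes, tibble(
        variant_id = out$variant_id[!testable],
        note = sprintf("not testable in screen '%s'", name)
      ))
    }
    if (!any(testable)) next
    threshold <- alpha / sum(testable)
    assoc <- testable & scr$p_value[hit] < threshold
    if (any(assoc)) {
      reason <- if (identical(name, "outcome")) "outcome-associated"
                else paste0("confounder:", name)
      removed <- bind_rows(removed, tibble(
        variant_id = out$variant_id[assoc], reason = reason
      ))
      out <- out[!assoc, ]
    }
  }
  attr(out, "removed") <- removed
  attr(out, "notes") <- notes
  out
}

#' Find LD proxies for variants missing from the outcome dataset
#'
#' For each missing variant the outcome-present variant with the highest
#' r2 strictly above `r2_min` is chosen; ties are broken by the smaller
#' outcome p-value, then by variant id. Variants with no qualifying proxy are
#' reported in the `"unproxied"` attribute.
#'
#' @param missing Character vector of instrument ids absent from the outcome.
#' @param ld An [ld_reference()].
#' @param outcome Outcome `gwas_sumstats`.
#' @param r2_min Minimum (exclusive) r2 for a proxy (default 0.9).
#' @return Tibble with columns `variant_id`, `proxy_id`, `r2`; attribute
#'   `"unproxied"` lists ids with no substitute.
#' @export
find_proxies <- function(missing, ld, outcome, r2_min = 0.9) {
  found <- tibble(variant_id = character(), proxy_id = character(),
                  r2 = numeric())
  unproxied <- character()
  outcome_ids <- outcome$variant_id
  for (id in missing) {
    cand <- ld$pairs %>%
      filter(.data$variant_a == id, .data$variant_b %in% outcome_ids,
             .data$r2 > r2_min)
    if (nrow(cand) == 0) {
      unproxied <- c(unproxied, id)
      next
    }
    cand$out_p <- outcome$p_value[match(cand$variant_b, outcome_ids)]
    best <- cand %>%
      arrange(dplyr::desc(.data$r2), .data$out_p, .data$variant_b) %>%
      head(1)
    found <- bind_rows(found, tibble(variant_id = id,
                                     proxy_id = best$variant_b,
                                     r2 = best$r2))
  }
  attr(found, "unproxied") <- unproxied
  found
}
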