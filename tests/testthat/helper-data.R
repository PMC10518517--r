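# Shared builders for small in-code fixtures.

# A minimal valid summary table with `n` rows.
make_summary_tbl <- function(n = 3, p_value = 1e-10, beta = 0.1) {
  tibble::tibble(
    variant_id = sprintf("rs%d", seq_len(n)),
    chromosome = "1",
    position = seq_len(n) * 1000L,
    effect_allele = "A",
    other_allele = "G",
    eaf = 0.3,
    beta = beta,
    se = 0.01,
    p_value = p_value,
    n = 10000
  )
}

make_sumstats <- function(n = 3, trait_id = "trait", ...) {
  bidirmr::gwas_sumstats(make_summary_tbl(n, ...), trait_id)
}

# Harmonized-shape tibble straight from per-variant effects.
make_harmonized_tbl <- function(gamma, Gamma, se_gamma = 0.01,
                                se_Gamma = 0.05) {
  tibble::tibble(
    variant_id = sprintf("rs%d", seq_along(gamma)),
    gamma = gamma,
    se_gamma = rep_len(se_gamma, length(gamma)),
    Gamma = Gamma,
    se_Gamma = rep_len(se_Gamma, length(gamma))
  )
}

# Simulated pair -> harmonized set on the analysis (log-odds) scale.
harmonize_pair <- function(pair) {
  outcome <- pair$outcome
  if (identical(attr(outcome, "scale"), "linear-boltlmm")) {
    outcome <- bidirmr::convert_boltlmm_to_logor(outcome)
  }
  suppressWarnings(bidirmr::harmonize(pair$exposure, outcome))
}
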