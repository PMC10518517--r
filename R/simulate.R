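# Synthetic two-sample GWAS summary statistics with known ground truth:
# causal effect, pleiotropy regime, LD-block structure, and allele-encoding
# quirks (palindromes, strand flips, allele swaps, outcome missingness).

#' Define a simulation scenario
#'
#' A scenario fixes the generative model behind a simulated exposure-outcome
#' pair. True instrument effects \eqn{\gamma_j} are drawn from
#' N(`gamma_mean`, `gamma_sd`); per-variant standard errors follow the
#' standardized-trait approximation
#' \eqn{\sigma \approx 1/\sqrt{2\,EAF(1-EAF)\,N}}; true outcome effects are
#' \eqn{\Gamma_j = \theta\gamma_j + \alpha_j}, with the pleiotropy term
#' \eqn{\alpha_j} controlled by `pleiotropy_mode`:
#' \describe{
#'   \item{none}{\eqn{\alpha_j = 0}.}
#'   \item{balanced}{\eqn{\alpha_j \sim N(0, sd)} (mean forced to zero).}
#'   \item{directional}{\eqn{\alpha_j \sim N(mean, sd)}, applied to a
#'     fraction `pleiotropy_frac` of instruments (InSIDE holds).}
#'   \item{inside_violated}{\eqn{\alpha_j = \rho\gamma_j + N(0, sd)}, which
#'     correlates pleiotropy with instrument strength.}
#' }
#' Binary outcomes are emitted on the BOLT-LMM linear scale (log-odds effects
#' multiplied by \eqn{\mu(1-\mu)}) so the conversion path is exercised.
#'
#' @param n_snps Number of candidate instruments J.
#' @param theta True causal effect of the exposure on the outcome
#'   (log odds ratio per exposure unit for binary outcomes).
#' @param gamma_mean,gamma_sd Mean and SD of the true instrument effects.
#' @param n_exposure,n_outcome GWAS sample sizes governing the SEs. Defaults
#'   mirror a cytokine GWAS meta-analysis (8 293) and a biobank disease GWAS
#'   (216 569 participants).
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violated"`.
#' @param pleiotropy_mean,pleiotropy_sd Parameters of the pleiotropy
#'   distribution.
#' @param pleiotropy_frac Fraction of instruments receiving the pleiotropic
#'   effect under `directional` (default 1).
#' @param pleiotropy_rho Slope linking pleiotropy to instrument strength
#'   under `inside_violated`.
#' @param outcome_binary Is the outcome a binary disease trait?
#' @param case_fraction Case fraction of a binary outcome; default
#'   470/216569, a rare-disease biobank setting.
#' @param ld_blocks Optional data frame (`size`, `r2`) of LD blocks; listed
#'   blocks are filled with consecutive variants sharing within-block `r2`,
#'   remaining variants are unlinked.
#' @param palindrome_rate,strand_flip_rate,allele_swap_rate,missing_in_outcome_rate
#'   Fractions in [0, 1]: variants given A/T or C/G alleles; outcome rows
#'   re-encoded on the opposite strand; outcome rows re-encoded with swapped
#'   alleles (beta negated, EAF complemented); outcome rows removed.
#' @param seed RNG seed; the emitted tables are a deterministic function of
#'   the scenario including the seed.
#' @return A list of class `mr_scenario`.
#' @export
mr_scenario <- function(n_snps = 30, theta = 0, gamma_mean = 0.1,
                        gamma_sd = 0.03, n_exposure = 8293,
                        n_outcome = 216569,
                        pleiotropy_mode = c("none", "balanced", "directional",
                                            "inside_violated"),
                        pleiotropy_mean = 0, pleiotropy_sd = 0,
                        pleiotropy_frac = 1, pleiotropy_rho = 0,
                        outcome_binary = TRUE, case_fraction = 470 / 216569,
                        ld_blocks = NULL, palindrome_rate = 0,
                        strand_flip_rate = 0, allele_swap_rate = 0,
                        missing_in_outcome_rate = 0, seed = NULL) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  rates <- c(palindrome_rate = palindrome_rate,
             strand_flip_rate = strand_flip_rate,
             allele_swap_rate = allele_swap_rate,
             missing_in_outcome_rate = missing_in_outcome_rate,
             pleiotropy_frac = pleiotropy_frac)
  for (nm in names(rates)) assert_scalar_number(rates[[nm]], nm, 0, 1)
  if (pleiotropy_mode == "balanced" && pleiotropy_mean != 0) {
    abort("Balanced pleiotropy requires pleiotropy_mean = 0.")
  }
  if (outcome_binary) {
    assert_scalar_number(case_fraction, "case_fraction", 0, 1, open = TRUE)
  }
  if (!is.null(ld_blocks)) {
    ld_blocks <- as_tibble(ld_blocks)
    stopifnot(all(c("size", "r2") %in% names(ld_blocks)))
    if (sum(ld_blocks$size) > n_snps) {
      abort("LD blocks cannot contain more variants than n_snps.")
    }
  }
  structure(
    list(
      n_snps = n_snps, theta = theta, gamma_mean = gamma_mean,
      gamma_sd = gamma_sd, n_exposure = n_exposure, n_outcome = n_outcome,
      pleiotropy_mode = pleiotropy_mode, pleiotropy_mean = pleiotropy_mean,
      pleiotropy_sd = pleiotropy_sd, pleiotropy_frac = pleiotropy_frac,
      pleiotropy_rho = pleiotropy_rho, outcome_binary = outcome_binary,
      case_fraction = case_fraction, ld_blocks = ld_blocks,
      palindrome_rate = palindrome_rate,
      strand_flip_rate = strand_flip_rate,
      allele_swap_rate = allele_swap_rate,
      missing_in_outcome_rate = missing_in_outcome_rate, seed = seed
    ),
    class = "mr_scenario"
  )
}

non_palindromic_pairs <- matrix(c(
  "A", "C", "A", "G", "C", "A", "C", "T",
  "G", "A", "G", "T", "T", "C", "T", "G"
), ncol = 2, byrow = TRUE)

#' Simulate a two-sample exposure/outcome summary-statistic pair
#'
#' Realizes a scenario: draws true and observed per-variant effects, assigns
#' alleles (with the configured palindrome rate), applies outcome-side
#' encoding quirks (strand flips, allele swaps, missingness), emits binary
#' outcomes on the BOLT-LMM linear scale, and returns the ground truth.
#'
#' @param scenario An [mr_scenario()].
#' @param exposure_id,outcome_id Trait labels for the emitted datasets.
#' @return List with `exposure` and `outcome` (`gwas_sumstats`), `ld` (an
#'   [ld_reference()], `NULL` without LD blocks), and `truth` (a list with
#'   `theta`, `case_fraction`, conversion `divisor`, and a per-variant tibble
#'   `snps` of true `gamma`, `alpha`, `Gamma`, block, and quirk indicators).
#' @export
simulate_mr_pair <- function(scenario, exposure_id = "exposure",
                             outcome_id = "outcome") {
  stopifnot(inherits(scenario, "mr_scenario"))
  s <- scenario
  with_seed(s$seed, {
    J <- s$n_snps
    variant_id <- sprintf("rs%06d", seq_len(J))
    chromosome <- "1"
    position <- seq_len(J) * 50000L
    eaf <- runif(J, 0.05, 0.95)

    gamma_true <- rnorm(J, s$gamma_mean, s$gamma_sd)
    se_gamma <- 1 / sqrt(2 * eaf * (1 - eaf) * s$n_exposure)
    gamma_hat <- rnorm(J, gamma_true, se_gamma)

    alpha <- rep(0, J)
    if (s$pleiotropy_mode == "balanced") {
      alpha <- rnorm(J, 0, s$pleiotropy_sd)
    } else if (s$pleiotropy_mode == "directional") {
      n_pleio <- round(s$pleiotropy_frac * J)
      idx <- sample.int(J, n_pleio)
      alpha[idx] <- rnorm(n_pleio, s$pleiotropy_mean, s$pleiotropy_sd)
    } else if (s$pleiotropy_mode == "inside_violated") {
      alpha <- s$pleiotropy_rho * gamma_true + rnorm(J, 0, s$pleiotropy_sd)
    }
    Gamma_true <- s$theta * gamma_true + alpha
    se_Gamma <- 1 / sqrt(2 * eaf * (1 - eaf) * s$n_outcome)
    Gamma_hat <- rnorm(J, Gamma_true, se_Gamma)

    # Allele assignment (exposure orientation).
    palindromic <- runif(J) < s$palindrome_rate
    pal_choice <- sample(c("AT", "TA", "CG", "GC"), J, replace = TRUE)
    np_choice <- sample.int(nrow(non_palindromic_pairs), J, replace = TRUE)
    effect_allele <- ifelse(palindromic, substr(pal_choice, 1, 1),
                            non_palindromic_pairs[np_choice, 1])
    other_allele <- ifelse(palindromic, substr(pal_choice, 2, 2),
                           non_palindromic_pairs[np_choice, 2])

    exposure <- tibble(
      variant_id = variant_id, chromosome = chromosome, position = position,
      effect_allele = effect_allele, other_allele = other_allele,
      eaf = eaf, beta = gamma_hat, se = se_gamma,
      p_value = z_pvalue(gamma_hat, se_gamma), n = s$n_exposure
    )

    # Outcome encoding quirks.
    out_ea <- effect_allele
    out_oa <- other_allele
    out_beta <- Gamma_hat
    out_eaf <- eaf
    swapped <- runif(J) < s$allele_swap_rate
    out_ea[swapped] <- other_allele[swapped]
    out_oa[swapped] <- effect_allele[swapped]
    out_beta[swapped] <- -out_beta[swapped]
    out_eaf[swapped] <- 1 - out_eaf[swapped]
    flipped <- runif(J) < s$strand_flip_rate
    out_ea[flipped] <- unname(allele_complement[out_ea[flipped]])
    out_oa[flipped] <- unname(allele_complement[out_oa[flipped]])
    missing <- runif(J) < s$missing_in_outcome_rate

    divisor <- if (s$outcome_binary) s$case_fraction * (1 - s$case_fraction)
               else NA_real_
    scale_mult <- if (s$outcome_binary) divisor else 1
    outcome <- tibble(
      variant_id = variant_id, chromosome = chromosome, position = position,
      effect_allele = out_ea, other_allele = out_oa,
      eaf = out_eaf, beta = out_beta * scale_mult,
      se = se_Gamma * scale_mult,
      p_value = z_pvalue(Gamma_hat, se_Gamma), n = s$n_outcome
    )[!missing, ]

    # LD blocks: consecutive variants share the block's r2.
    block <- rep(NA_integer_, J)
    ld <- NULL
    if (!is.null(s$ld_blocks) && nrow(s$ld_blocks) > 0) {
      pos <- 1L
      pairs <- list()
      for (b in seq_len(nrow(s$ld_blocks))) {
        size <- s$ld_blocks$size[b]
        members <- seq.int(pos, pos + size - 1L)
        block[members] <- b
        if (size > 1) {
          combo <- utils::combn(members, 2)
          pairs[[b]] <- tibble(
            variant_a = variant_id[combo[1, ]],
            variant_b = variant_id[combo[2, ]],
            r2 = s$ld_blocks$r2[b]
          )
        }
        pos <- pos + size
      }
      ld <- ld_reference(bind_rows(pairs))
    }

    truth <- list(
      theta = s$theta,
      case_fraction = if (s$outcome_binary) s$case_fraction else NA_real_,
      divisor = divisor,
      scenario = s,
      snps = tibble(
        variant_id = variant_id, gamma = gamma_true, alpha = alpha,
        Gamma = Gamma_true, block = block, palindromic = palindromic,
        swapped = swapped, flipped = flipped, missing_in_outcome = missing
      )
    )
    list(
      exposure = gwas_sumstats(exposure, exposure_id,
                               trait_type = "continuous",
                               scale = "inverse-normal"),
      outcome = if (s$outcome_binary) {
        gwas_sumstats(outcome, outcome_id, trait_type = "binary",
                      scale = "linear-boltlmm",
                      case_fraction = s$case_fraction)
      } else {
        gwas_sumstats(outcome, outcome_id, trait_type = "continuous",
                      scale = "inverse-normal")
      },
      ld = ld,
      truth = truth
    )
  })
}

#' Simulate a panel of inflammatory-factor GWASs plus one disease GWAS
#'
#' Emulates the data shape of a bidirectional screen of circulating
#' inflammatory factors against a rare binary disease: `factor_count`
#' inverse-normal cytokine-like exposures (GWAS n = 8 293), two natural-log
#' acute-phase proteins ("CRP", n = 206 158; "PCT", n = 3 301), and one
#' binary disease trait emitted on the BOLT-LMM linear scale with case
#' fraction 470/216569. Each factor contributes its own instrument variants;
#' the disease dataset carries outcome rows for all of them plus its own
#' `n_disease_snps` instruments (effects drawn to clear the relaxed 1e-5
#' threshold), which every factor dataset carries as outcome rows for the
#' reverse direction.
#'
#' By default every factor is causally null except one designated active
#' factor with forward effect `theta_active` (log OR 0.351, i.e. OR 1.42),
#' so panel-level multiple-testing behaviour is testable; reverse effects
#' are all null.
#'
#' @param factor_count Number of cytokine-like factors (default 41).
#' @param n_snps_per_factor Candidate instruments per factor.
#' @param active_factor Index of the factor with a real forward effect
#'   (`0` for none).
#' @param theta_active Forward log odds ratio of the active factor.
#' @param n_disease_snps Disease instrument variants (default 18).
#' @param case_fraction Disease case fraction.
#' @param seed RNG seed for the whole panel.
#' @return List with `factors` (named list of `gwas_sumstats`), `crp`,
#'   `pct`, `disease`, and `truth` (per-trait tibble of true forward and
#'   reverse effects plus the conversion `divisor`).
#' @export
simulate_mr_panel <- function(factor_count = 41, n_snps_per_factor = 30,
                              active_factor = 8, theta_active = log(1.42),
                              n_disease_snps = 18,
                              case_fraction = 470 / 216569, seed = NULL) {
  if (factor_count < 1) abort("factor_count must be at least 1.")
  if (active_factor > factor_count) {
    abort("active_factor must be 0 or a factor index.")
  }
  divisor <- case_fraction * (1 - case_fraction)
  n_traits <- factor_count + 2
  seeds <- derive_seeds(seed, 2 * n_traits + 1)

  specs <- tibble(
    trait_id = c(sprintf("factor_%02d", seq_len(factor_count)), "CRP", "PCT"),
    scale = c(rep("inverse-normal", factor_count), "natural-log",
              "natural-log"),
    n = c(rep(8293, factor_count), 206158, 3301),
    theta_forward = 0,
    theta_reverse = 0
  )
  if (active_factor >= 1) {
    specs$theta_forward[active_factor] <- theta_active
  }

  # Disease's own instruments (exposure role in the reverse direction),
  # drawn on the log-odds scale with effects strong enough for the relaxed
  # threshold given the disease GWAS precision.
  n_disease <- 216569
  disease_rows <- with_seed(seeds[[2 * n_traits + 1]], {
    eaf <- runif(n_disease_snps, 0.05, 0.95)
    se <- 1 / sqrt(2 * eaf * (1 - eaf) * n_disease) # log-odds scale
    gamma_true <- rnorm(n_disease_snps, 8 * mean(se), 2 * mean(se))
    gamma_hat <- rnorm(n_disease_snps, gamma_true, se)
    np <- sample.int(nrow(non_palindromic_pairs), n_disease_snps,
                     replace = TRUE)
    list(
      tab = tibble(
        variant_id = sprintf("rsD%05d", seq_len(n_disease_snps)),
        chromosome = "2",
        position = seq_len(n_disease_snps) * 50000L,
        effect_allele = non_palindromic_pairs[np, 1],
        other_allele = non_palindromic_pairs[np, 2],
        eaf = eaf, beta = gamma_hat, se = se,
        p_value = z_pvalue(gamma_hat, se), n = n_disease
      ),
      gamma_true = gamma_true
    )
  })

  factors <- list()
  disease_outcome_rows <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(specs))) {
    pair <- simulate_mr_pair(
      mr_scenario(
        n_snps = n_snps_per_factor,
        theta = specs$theta_forward[i],
        n_exposure = specs$n[i],
        case_fraction = case_fraction,
        seed = seeds[[i]]
      ),
      exposure_id = specs$trait_id[i], outcome_id = "disease"
    )
    fx <- as_tibble(pair$exposure)
    # Re-key variants per trait so the union panel has unique ids.
    prefix <- sprintf("rs%s", gsub("[^0-9A-Za-z]", "", specs$trait_id[i]))
    fx$variant_id <- sprintf("%s_%03d", prefix, seq_len(nrow(fx)))
    out_rows <- as_tibble(pair$outcome)
    out_rows$variant_id <- fx$variant_id[match(out_rows$position,
                                               fx$position)]
    out_rows$chromosome <- as.character(2 + i)
    fx$chromosome <- as.character(2 + i)
    disease_outcome_rows[[i]] <- out_rows

    # Reverse-direction outcome rows: disease instruments measured on the
    # factor's scale, with the trait's null (or specified) reverse effect.
    rev_rows <- with_seed(seeds[[n_traits + i]], {
      se <- 1 / sqrt(2 * disease_rows$tab$eaf *
                       (1 - disease_rows$tab$eaf) * specs$n[i])
      beta_true <- specs$theta_reverse[i] * disease_rows$gamma_true
      beta_hat <- rnorm(n_disease_snps, beta_true, se)
      disease_rows$tab %>%
        mutate(beta = beta_hat, se = se,
               p_value = z_pvalue(beta_hat, se), n = specs$n[i])
    })
    tab <- bind_rows(fx, rev_rows)
    factors[[specs$trait_id[i]]] <- gwas_sumstats(
      tab, specs$trait_id[i], trait_type = "continuous",
      scale = specs$scale[i]
    )
    truth_rows[[i]] <- tibble(
      trait_id = specs$trait_id[i],
      theta_forward = specs$theta_forward[i],
      theta_reverse = specs$theta_reverse[i]
    )
  }

  disease_tab <- bind_rows(
    disease_rows$tab %>%
      mutate(beta = .data$beta * divisor, se = .data$se * divisor),
    bind_rows(disease_outcome_rows)
  )
  disease <- gwas_sumstats(disease_tab, "disease", trait_type = "binary",
                           scale = "linear-boltlmm",
                           case_fraction = case_fraction)

  crp_pct <- factors[c("CRP", "PCT")]
  factors[c("CRP", "PCT")] <- NULL
  list(
    factors = factors,
    crp = crp_pct$CRP,
    pct = crp_pct$PCT,
    disease = disease,
    truth = list(
      traits = bind_rows(truth_rows),
      divisor = divisor,
      case_fraction = case_fraction,
      disease_instruments = disease_rows$tab$variant_id
    )
  )
}
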