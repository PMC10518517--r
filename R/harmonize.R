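# Aligning exposure and outcome associations to a common effect allele.

allele_complement <- c(A = "T", T = "A", C = "G", G = "C")

#' Is an allele pair palindromic?
#'
#' A palindromic (ambiguous) variant carries the same pair of alleles on both
#' strands: A/T or C/G. Its orientation cannot be resolved from the alleles,
#' so the pipeline excludes it during harmonization.
#'
#' @param effect_allele,other_allele Character vectors of single bases
#'   (vectorized).
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele)
  oa <- toupper(other_allele)
  unname(allele_complement[ea] == oa)
}

#' Harmonize exposure and outcome associations
#'
#' Matches variants by id and aligns the outcome association to the
#' exposure's effect allele. For each shared variant:
#' \itemize{
#'   \item alleles already matched: the outcome effect is copied;
#'   \item alleles swapped (outcome effect allele equals the exposure's other
#'     allele): the outcome beta is negated and its EAF replaced by 1 - EAF;
#'   \item alleles matching only after complementing the outcome pair: the
#'     strand is corrected, then the copy/swap rule applies;
#'   \item palindromic (A/T or C/G) in either dataset: excluded,
#'     reason `"palindromic"`;
#'   \item irreconcilable alleles: excluded, reason `"allele mismatch"`.
#' }
#' Exposure variants absent from the outcome are excluded with reason
#' `"missing in outcome"`. The magnitude of the outcome effect and its SE are
#' never altered; only the sign (and EAF orientation) can change. An aligned
#' EAF differing from the exposure EAF by more than 0.2 triggers a warning
#' only, never an exclusion.
#'
#' @param exposure,outcome `gwas_sumstats` (or data frames with the canonical
#'   columns); `exposure` is usually the selected instrument rows.
#' @param exposure_id,outcome_id Trait labels; default to the datasets'
#'   metadata.
#' @return A tibble of class `mr_harmonized` with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `gamma`, `se_gamma`, `p_exposure`,
#'   `eaf_exposure`, `Gamma`, `se_Gamma`, `p_outcome`, `eaf_outcome`,
#'   `action`; attributes `exposure_id`, `outcome_id`, and `exclusions`
#'   (tibble of `variant_id`, `reason`).
#' @export
harmonize <- function(exposure, outcome, exposure_id = NULL,
                      outcome_id = NULL) {
  exposure_id <- exposure_id %||% attr(exposure, "trait_id") %||% "exposure"
  outcome_id <- outcome_id %||% attr(outcome, "trait_id") %||% "outcome"
  exp <- as_tibble(exposure)
  out <- as_tibble(outcome)

  hit <- match(exp$variant_id, out$variant_id)
  exclusions <- tibble(variant_id = exp$variant_id[is.na(hit)],
                       reason = "missing in outcome")

  shared <- which(!is.na(hit))
  rows <- vector("list", length(shared))
  for (k in seq_along(shared)) {
    i <- shared[k]
    j <- hit[i]
    e_ea <- exp$effect_allele[i]; e_oa <- exp$other_allele[i]
    o_ea <- out$effect_allele[j]; o_oa <- out$other_allele[j]
    id <- exp$variant_id[i]

    if (is_palindromic(e_ea, e_oa) || is_palindromic(o_ea, o_oa)) {
      exclusions <- bind_rows(exclusions,
                              tibble(variant_id = id, reason = "palindromic"))
      next
    }

    action <- NULL
    if (o_ea == e_ea && o_oa == e_oa) {
      action <- "copy"
    } else if (o_ea == e_oa && o_oa == e_ea) {
      action <- "swap"
    } else {
      c_ea <- unname(allele_complement[o_ea])
      c_oa <- unname(allele_complement[o_oa])
      if (c_ea == e_ea && c_oa == e_oa) {
        action <- "flip"
      } else if (c_ea == e_oa && c_oa == e_ea) {
        action <- "flip_swap"
      }
    }
    if (is.null(action)) {
      exclusions <- bind_rows(exclusions,
                              tibble(variant_id = id,
                                     reason = "allele mismatch"))
      next
    }
    swap <- action %in% c("swap", "flip_swap")
    rows[[k]] <- tibble(
      variant_id = id,
      effect_allele = e_ea,
      other_allele = e_oa,
      gamma = exp$beta[i],
      se_gamma = exp$se[i],
      p_exposure = exp$p_value[i],
      eaf_exposure = exp$eaf[i],
      Gamma = if (swap) -out$beta[j] else out$beta[j],
      se_Gamma = out$se[j],
      p_outcome = out$p_value[j],
      eaf_outcome = if (swap) 1 - out$eaf[j] else out$eaf[j],
      action = action
    )
  }
  snps <- bind_rows(rows)
  if (nrow(snps) == 0) {
    cond <- rlang::error_cnd(
      class = "bidirmr_empty_harmonized",
      message = sprintf(
        "No variants survive harmonization of '%s' on '%s'.",
        exposure_id, outcome_id
      ),
      exclusions = exclusions
    )
    rlang::cnd_signal(cond)
  }
  discordant <- abs(snps$eaf_exposure - snps$eaf_outcome) > 0.2
  if (any(discordant)) {
    warn(sprintf(
      "%d harmonized variant(s) have |EAF difference| > 0.2 (%s); check strand assumptions.",
      sum(discordant),
      paste(head(snps$variant_id[discordant], 5), collapse = ", ")
    ))
  }
  new_mr_harmonized(snps, exposure_id, outcome_id, exclusions)
}

new_mr_harmonized <- function(snps, exposure_id, outcome_id, exclusions) {
  structure(
    snps,
    class = c("mr_harmonized", class(tibble())),
    exposure_id = exposure_id,
    outcome_id = outcome_id,
    exclusions = exclusions
  )
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat(sprintf("<mr_harmonized> %s -> %s: %d variant(s), %d excluded\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"), nrow(x),
              nrow(attr(x, "exclusions"))))
  NextMethod()
}

#' @rdname harmonize
#' @param x An `mr_harmonized` object.
#' @param ... Unused.
#' @method tidy mr_harmonized
#' @export
tidy.mr_harmonized <- function(x, ...) {
  as_tibble(x)
}

#' Exclusion log of a harmonized set
#'
#' @param x An `mr_harmonized` object.
#' @return Tibble of (`variant_id`, `reason`).
#' @export
harmonization_exclusions <- function(x) {
  attr(x, "exclusions")
}
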