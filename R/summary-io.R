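# Reading, validating, and rescaling GWAS summary-statistic tables.

summary_cols <- c(
  "variant_id", "chromosome", "position", "effect_allele", "other_allele",
  "eaf", "beta", "se", "p_value", "n"
)

#' Construct a validated GWAS summary-statistics table
#'
#' Takes a data frame of per-variant associations and attaches the trait
#' metadata that downstream Mendelian randomization steps need: trait id,
#' whether the trait is binary, the scale its effect sizes are reported on,
#' and (for binary traits) the case fraction used to convert linear
#' mixed-model effects to log odds ratios.
#'
#' Rows violating the per-variant invariants (non-ACGT or identical alleles,
#' non-positive SE, effect-allele frequency outside (0,1), p-value outside
#' (0,1], missing numbers) are dropped and recorded in the `"dropped"`
#' attribute with a reason. Among duplicated variant ids the smallest-p row is
#' kept. p-values of exactly zero are replaced by the smallest positive
#' normal double so that -log10(p) stays finite; such rows are logged, not
#' dropped.
#'
#' @param data Data frame with columns `variant_id`, `chromosome`, `position`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p_value`, `n`.
#' @param trait_id Character label for the trait.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param scale Scale of `beta`: `"inverse-normal"`, `"natural-log"`,
#'   `"linear-boltlmm"`, or `"log-odds"`.
#' @param case_fraction Case fraction \eqn{\mu \in (0,1)} of a binary trait;
#'   required before [convert_boltlmm_to_logor()] can run.
#' @return A tibble of class `gwas_sumstats` with attributes `trait_id`,
#'   `trait_type`, `scale`, `case_fraction`, and `dropped` (a tibble of
#'   `variant_id`, `reason`).
#' @seealso [read_gwas_summary()] to build one straight from a TSV file.
#' @export
gwas_sumstats <- function(data, trait_id,
                          trait_type = c("continuous", "binary"),
                          scale = c("inverse-normal", "natural-log",
                                    "linear-boltlmm", "log-odds"),
                          case_fraction = NULL) {
  trait_type <- match.arg(trait_type)
  scale <- match.arg(scale)
  missing_cols <- setdiff(summary_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Summary table for '%s' is missing required column(s): %s",
                  trait_id, paste(missing_cols, collapse = ", ")))
  }
  if (!is.null(case_fraction)) {
    assert_scalar_number(case_fraction, "case_fraction", 0, 1, open = TRUE)
  }
  if (trait_type == "binary" && scale == "linear-boltlmm" &&
      is.null(case_fraction)) {
    warn(sprintf(
      "Trait '%s' is binary on the linear-boltlmm scale but has no case_fraction; set it before converting to log odds.",
      trait_id
    ))
  }

  x <- as_tibble(data)[, summary_cols]
  x$variant_id <- as.character(x$variant_id)
  x$chromosome <- as.character(x$chromosome)
  x$position <- as.integer(x$position)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))

  num <- c("eaf", "beta", "se", "p_value", "n")
  for (col in num) x[[col]] <- as.numeric(x[[col]])

  dropped <- tibble(variant_id = character(), reason = character())
  flag <- function(bad, reason) {
    bad[is.na(bad)] <- TRUE
    dropped <<- bind_rows(dropped,
                          tibble(variant_id = x$variant_id[bad],
                                 reason = reason))
    x <<- x[!bad, ]
  }
  bases <- c("A", "C", "G", "T")
  flag(!(x$effect_allele %in% bases) | !(x$other_allele %in% bases),
       "non-SNP or invalid allele")
  flag(x$effect_allele == x$other_allele, "identical alleles")
  flag(!(x$se > 0), "nonpositive SE")
  flag(!(x$eaf > 0 & x$eaf < 1), "EAF outside (0,1)")
  flag(!(x$p_value >= 0 & x$p_value <= 1), "p-value outside [0,1]")
  flag(is.na(x$beta) | is.na(x$n), "missing beta or n")

  zero_p <- which(x$p_value == 0)
  if (length(zero_p) > 0) {
    x$p_value[zero_p] <- .Machine$double.xmin
    dropped <- bind_rows(dropped,
                         tibble(variant_id = x$variant_id[zero_p],
                                reason = "p = 0 replaced by double.xmin (kept)"))
  }

  if (anyDuplicated(x$variant_id)) {
    keep <- x %>%
      mutate(.row = row_number()) %>%
      group_by(.data$variant_id) %>%
      slice_min(.data$p_value, n = 1, with_ties = FALSE) %>%
      ungroup() %>%
      pull(.data$.row)
    dup <- setdiff(seq_len(nrow(x)), keep)
    dropped <- bind_rows(dropped,
                         tibble(variant_id = x$variant_id[dup],
                                reason = "duplicate variant_id (larger p)"))
    x <- x[sort(keep), ]
  }

  if (nrow(x) == 0) {
    abort(sprintf("No valid rows remain for trait '%s'.", trait_id))
  }

  structure(
    x,
    class = c("gwas_sumstats", class(tibble())),
    trait_id = trait_id,
    trait_type = trait_type,
    scale = scale,
    case_fraction = case_fraction,
    dropped = dropped
  )
}

#' Read a GWAS summary-statistics TSV
#'
#' Reads a tab-separated summary-statistics file, renames columns to the
#' canonical names via `col_map`, and validates it with [gwas_sumstats()].
#'
#' @inheritParams gwas_sumstats
#' @param path Path to a tab-separated file with a header row.
#' @param col_map Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(beta = "Effect", se = "StdErr")`.
#'   Unmapped canonical names are looked up verbatim.
#' @return A `gwas_sumstats` tibble.
#' @export
read_gwas_summary <- function(path, trait_id,
                              trait_type = c("continuous", "binary"),
                              scale = c("inverse-normal", "natural-log",
                                        "linear-boltlmm", "log-odds"),
                              case_fraction = NULL, col_map = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    bad <- setdiff(unname(col_map), names(raw))
    if (length(bad) > 0) {
      abort(sprintf("col_map points at absent column(s): %s",
                    paste(bad, collapse = ", ")))
    }
    names(raw)[match(unname(col_map), names(raw))] <- names(col_map)
  }
  gwas_sumstats(raw, trait_id = trait_id, trait_type = trait_type,
                scale = scale, case_fraction = case_fraction)
}

#' Trait metadata of a summary-statistics table
#'
#' @param x A `gwas_sumstats` object.
#' @return A list with `trait_id`, `trait_type`, `scale`, `case_fraction`.
#' @export
trait_meta <- function(x) {
  list(
    trait_id = attr(x, "trait_id"),
    trait_type = attr(x, "trait_type"),
    scale = attr(x, "scale"),
    case_fraction = attr(x, "case_fraction")
  )
}

#' Convert BOLT-LMM linear-scale effects for a binary trait to log odds ratios
#'
#' BOLT-LMM reports linear mixed-model effect sizes even for binary traits.
#' For a disease with case fraction \eqn{\mu}, the linear effect \eqn{\beta}
#' approximates the log odds ratio after rescaling:
#' \deqn{\log OR \approx \beta / (\mu (1 - \mu))}
#' and the standard error is divided by the same factor \eqn{\mu(1-\mu)}.
#' p-values are scale-free and unchanged; the per-variant z-score
#' \eqn{\beta/\mathrm{SE}} is preserved exactly.
#'
#' @param data A binary-trait `gwas_sumstats` on the `linear-boltlmm` scale.
#' @param case_fraction Optional override of the dataset's stored case
#'   fraction.
#' @return The dataset with rescaled `beta` and `se` and scale `"log-odds"`.
#' @export
convert_boltlmm_to_logor <- function(data, case_fraction = NULL) {
  meta <- trait_meta(data)
  if (identical(meta$scale, "log-odds")) {
    warn("Dataset is already on the log-odds scale; returning unchanged.")
    return(data)
  }
  if (!identical(meta$trait_type, "binary") ||
      !identical(meta$scale, "linear-boltlmm")) {
    abort("convert_boltlmm_to_logor() needs a binary trait on the linear-boltlmm scale.")
  }
  mu <- case_fraction %||% meta$case_fraction
  if (is.null(mu)) {
    abort("case_fraction is required to convert linear-boltlmm effects to log odds.")
  }
  assert_scalar_number(mu, "case_fraction", 0, 1, open = TRUE)
  divisor <- mu * (1 - mu)
  out <- data
  out$beta <- out$beta / divisor
  out$se <- out$se / divisor
  attr(out, "scale") <- "log-odds"
  attr(out, "case_fraction") <- mu
  out
}

#' Write MR result rows to a tab-separated file
#'
#' Writes one row per (trait pair, method) with full double precision, so a
#' write-then-read round trip reproduces every numeric field to at least 10
#' significant digits.
#'
#' @param rows Data frame of result rows (as produced by [tidy()] on fitted
#'   objects or by the pipeline).
#' @param path Output file path.
#' @return `rows`, invisibly.
#' @export
write_mr_results <- function(rows, path) {
  readr::write_tsv(as_tibble(rows), path, progress = FALSE)
  invisible(rows)
}

#' @export
print.gwas_sumstats <- function(x, ...) {
  meta <- trait_meta(x)
  cat(sprintf("<gwas_sumstats> trait '%s' (%s, scale %s%s): %d variants\n",
              meta$trait_id, meta$trait_type, meta$scale,
              if (!is.null(meta$case_fraction))
                sprintf(", case fraction %.4g", meta$case_fraction) else "",
              nrow(x)))
  dropped <- attr(x, "dropped")
  if (!is.null(dropped) && nrow(dropped) > 0) {
    cat(sprintf("  %d row(s) dropped or amended on validation\n", nrow(dropped)))
  }
  NextMethod()
}
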