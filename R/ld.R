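# Offline LD reference: a symmetric table of pairwise r-squared values.

#' Build an LD reference from a pair table
#'
#' The pipeline never computes linkage disequilibrium from genotypes; it is
#' supplied as a local table of pairwise squared correlations. The table is
#' closed under symmetry on construction, self pairs are implied (r2 = 1),
#' and any absent pair is treated as r2 = 0.
#'
#' @param pairs Data frame with columns `variant_a`, `variant_b`, `r2`.
#' @param window Maximum base-pair distance at which pairs are considered
#'   linked by clumping (default 10 Mb).
#' @return An `ld_reference` object.
#' @export
ld_reference <- function(pairs, window = 1e7) {
  pairs <- as_tibble(pairs)
  need <- c("variant_a", "variant_b", "r2")
  if (!all(need %in% names(pairs))) {
    abort("LD pairs need columns variant_a, variant_b, r2.")
  }
  pairs <- pairs[, need]
  pairs$variant_a <- as.character(pairs$variant_a)
  pairs$variant_b <- as.character(pairs$variant_b)
  pairs$r2 <- as.numeric(pairs$r2)
  if (any(pairs$r2 < 0 | pairs$r2 > 1, na.rm = TRUE)) {
    abort("r2 values must lie in [0, 1].")
  }
  sym <- bind_rows(
    pairs,
    tibble(variant_a = pairs$variant_b, variant_b = pairs$variant_a,
           r2 = pairs$r2)
  ) %>%
    filter(.data$variant_a != .data$variant_b)
  if (nrow(sym) > 0) {
    sym <- sym %>%
      group_by(.data$variant_a, .data$variant_b) %>%
      summarise(r2 = max(.data$r2), .groups = "drop")
  }
  structure(list(pairs = sym, window = window), class = "ld_reference")
}

#' Read an LD reference from a tab-separated table
#'
#' @param path TSV with header columns `variant_a`, `variant_b`, `r2`.
#' @inheritParams ld_reference
#' @return An `ld_reference` object.
#' @export
read_ld_table <- function(path, window = 1e7) {
  ld_reference(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
               window = window)
}

#' Look up pairwise r-squared values
#'
#' @param ld An `ld_reference`.
#' @param a,b Character vectors of variant ids (recycled to common length).
#' @return Numeric vector of r2 values; 1 for self pairs, 0 for absent pairs.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_reference"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- ifelse(a == b, 1, 0)
  key <- paste(a, b, sep = "\r")
  tab_key <- paste(ld$pairs$variant_a, ld$pairs$variant_b, sep = "\r")
  hit <- match(key, tab_key)
  out[!is.na(hit)] <- ld$pairs$r2[hit[!is.na(hit)]]
  out
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("<ld_reference> %d directed pairs, window %s bp\n",
              nrow(x$pairs), format(x$window, big.mark = ",")))
  invisible(x)
}
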