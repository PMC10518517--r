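# Small deterministic fixtures (hard-coded, seed-free) used by the test
# suite and exportable as TSVs for external tools.

#' Deterministic worked fixtures
#'
#' Returns one of four hard-coded fixture families used to exercise exact
#' properties of the estimators and harmonization:
#' \describe{
#'   \item{egger_collinear}{Three instruments lying exactly on
#'     \eqn{\Gamma = 0.05 + 2\gamma}; Egger recovers slope 2 and intercept
#'     0.05 exactly.}
#'   \item{constant_ratio}{Four instruments with identical Wald ratio 2;
#'     every estimator returns 2 and Q = 0.}
#'   \item{presso_outlier}{Ten instruments on \eqn{\Gamma = 0.3\gamma} with
#'     one outcome effect shifted by +10 SE; the outlier framework must flag
#'     `rs_out`.}
#'   \item{harmonization_quirks}{A list of `exposure` and `outcome` tables
#'     covering the copy, swap, strand-flip, flip-swap, palindromic,
#'     allele-mismatch, and missing-in-outcome cases.}
#' }
#'
#' @param name Fixture name.
#' @return A tibble (or list of two tibbles for `harmonization_quirks`).
#' @export
mr_fixture <- function(name = c("egger_collinear", "constant_ratio",
                                "presso_outlier", "harmonization_quirks")) {
  name <- match.arg(name)
  switch(
    name,
    egger_collinear = tibble(
      variant_id = c("rs_a", "rs_b", "rs_c"),
      gamma = c(0.1, 0.2, 0.3),
      se_gamma = c(0.01, 0.01, 0.01),
      Gamma = c(0.25, 0.45, 0.65),
      se_Gamma = c(0.1, 0.1, 0.1)
    ),
    constant_ratio = tibble(
      variant_id = sprintf("rs_c%d", 1:4),
      gamma = c(0.1, 0.2, 0.3, 0.4),
      se_gamma = rep(0.01, 4),
      Gamma = c(0.2, 0.4, 0.6, 0.8),
      se_Gamma = c(0.05, 0.06, 0.07, 0.08)
    ),
    presso_outlier = {
      gamma <- c(0.08, 0.10, 0.12, 0.14, 0.16, 0.18, 0.20, 0.22, 0.24, 0.15)
      Gamma <- 0.3 * gamma
      se_Gamma <- rep(0.01, 10)
      Gamma[10] <- Gamma[10] + 10 * se_Gamma[10] # gross pleiotropic outlier
      tibble(
        variant_id = c(sprintf("rs_p%d", 1:9), "rs_out"),
        gamma = gamma,
        se_gamma = rep(0.005, 10),
        Gamma = Gamma,
        se_Gamma = se_Gamma
      )
    },
    harmonization_quirks = list(
      exposure = tibble(
        variant_id = sprintf("rs_h%d", 1:7),
        chromosome = "1",
        position = 1:7 * 1000L,
        effect_allele = c("A", "A", "A", "A", "A", "A", "A"),
        other_allele = c("G", "G", "G", "G", "T", "G", "G"),
        eaf = rep(0.3, 7),
        beta = rep(0.10, 7),
        se = rep(0.01, 7),
        p_value = rep(1e-10, 7),
        n = rep(10000, 7)
      ),
      outcome = tibble(
        variant_id = sprintf("rs_h%d", 1:6),
        chromosome = "1",
        position = 1:6 * 1000L,
        # copy, swap, strand flip, flip+swap, palindrome, mismatch
        effect_allele = c("A", "G", "T", "C", "A", "A"),
        other_allele = c("G", "A", "C", "T", "T", "C"),
        eaf = c(0.3, 0.7, 0.3, 0.7, 0.3, 0.3),
        beta = c(0.05, -0.05, 0.05, -0.05, 0.05, 0.05),
        se = rep(0.02, 6),
        p_value = rep(0.01, 6),
        n = rep(200000, 6)
      )
    )
  )
}

#' Write the fixture suite as tab-separated files
#'
#' @param out_dir Writable directory; created if absent.
#' @return Character vector of the files written, invisibly.
#' @export
make_fixture_suite <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (nm in c("egger_collinear", "constant_ratio", "presso_outlier")) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(mr_fixture(nm), path, progress = FALSE)
    files <- c(files, path)
  }
  hq <- mr_fixture("harmonization_quirks")
  for (part in names(hq)) {
    path <- file.path(out_dir, paste0("harmonization_quirks_", part, ".tsv"))
    readr::write_tsv(hq[[part]], path, progress = FALSE)
    files <- c(files, path)
  }
  invisible(files)
}
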