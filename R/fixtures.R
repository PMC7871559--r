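#' Bundled instrument tables for the worked example
#'
#' `load_fixture("5-oxoproline")` returns the 25-SNP instrument set for
#' the metabolite 5-oxoproline against intelligence, transcribed from
#' the published per-SNP table (exposure beta/SE/p from the metabolomics
#' GWAS of 7824 adults; outcome beta/SE/p from the intelligence GWAS
#' meta-analysis). Effect-allele frequencies and per-SNP sample sizes are
#' not printed there and are carried as `NA`; the exposure GWAS sample
#' size 7824 is the conventional `n_override` for strength statistics.
#' Both tables are flagged pre-harmonized: the printed effects are
#' already expressed on a common effect allele, so [harmonize_pair()]
#' pairs rows by SNP id without re-resolving alleles (three of the 25
#' SNPs are A/T palindromes and would otherwise be dropped).
#'
#' The other two names return *synthetic stand-ins* (files prefixed
#' `synthetic_`): instrument tables generated by [simulate_pair()] with
#' causal effects matching the published point estimates (-0.14 for
#' dihomo-linoleate, +0.01 for p-acetamidophenylglucuronide). The
#' per-SNP values are not the published supplementary tables, which are
#' not redistributed here; use them for pipeline exercises, not for
#' reproducing printed numbers.
#'
#' @param name one of `"5-oxoproline"`, `"dihomo-linoleate"`,
#'   `"p-acetamidophenylglucuronide"`.
#' @return A list with elements `exposure` and `outcome` (both
#'   [summary_table()], pre-harmonized) and `synthetic` (logical).
#' @examples
#' fx <- load_fixture("5-oxoproline")
#' nrow(fx$exposure)  # 25 instruments
#' @export
load_fixture <- function(name) {
  files <- list(
    "5-oxoproline" = c("oxoproline_exposure.tsv",
                       "oxoproline_outcome.tsv"),
    "dihomo-linoleate" = c("synthetic_dihomo_linoleate_exposure.tsv",
                           "synthetic_dihomo_linoleate_outcome.tsv"),
    "p-acetamidophenylglucuronide" =
      c("synthetic_acetamidophenylglucuronide_exposure.tsv",
        "synthetic_acetamidophenylglucuronide_outcome.tsv"))
  if (length(name) != 1L || !name %in% names(files))
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; valid names: ", paste(names(files), collapse = ", "))
  paths <- vapply(files[[name]], function(f)
    system.file("extdata", f, package = "metamr", mustWork = TRUE),
    character(1))
  list(exposure = read_summary_stats(paths[1], trait_id = name,
                                     pre_harmonized = TRUE),
       outcome = read_summary_stats(paths[2], trait_id = "intelligence",
                                    pre_harmonized = TRUE),
       synthetic = grepl("^synthetic_", files[[name]][1]))
}
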