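#' GWAS summary-statistic tables
#'
#' A `summary_table` is a validated data frame of per-SNP association
#' statistics for one trait: one row per variant with columns `snp_id`,
#' `chrom`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`
#' and `n`. `beta` is the additive effect per copy of the effect allele,
#' `se` its standard error, `eaf` the effect-allele frequency and `n` the
#' GWAS sample size (`eaf`, `n` and `chrom` may be `NA`).
#'
#' Validation enforces: non-empty table, unique `snp_id`, single-letter
#' alleles in A/C/G/T with `effect_allele != other_allele`, `se > 0`,
#' `pval` in (0, 1] and `eaf` in (0, 1) where present. Every offending
#' row is reported by index; nothing is dropped silently.
#'
#' @param x data frame carrying (at least) the canonical columns above.
#'   Alleles are upper-cased; extra columns are discarded.
#' @param trait_id character scalar naming the trait the table describes.
#' @param pre_harmonized logical; `TRUE` marks a table whose rows are
#'   already expressed on a common effect allele with its partner table
#'   (e.g. a transcribed instrument table), so [harmonize_pair()] pairs
#'   rows by `snp_id` without re-resolving alleles.
#' @return An object of class `summary_table` (a data frame).
#' @examples
#' tab <- summary_table(data.frame(
#'   snp_id = c("rs1", "rs2"), effect_allele = c("A", "t"),
#'   other_allele = c("G", "c"), beta = c(0.1, -0.05),
#'   se = c(0.01, 0.02), pval = c(1e-8, 1e-6)), trait_id = "demo")
#' nrow(tab)
#' @seealso [read_summary_stats()], [load_fixture()]
#' @export
summary_table <- function(x, trait_id, pre_harmonized = FALSE) {
  stopifnot(is.data.frame(x), is.character(trait_id), length(trait_id) == 1L)
  canon <- c("snp_id", "chrom", "effect_allele", "other_allele",
             "eaf", "beta", "se", "pval", "n")
  for (col in c("chrom", "eaf", "n"))
    if (is.null(x[[col]])) x[[col]] <- NA
  need <- setdiff(canon, names(x))
  if (length(need))
    stop("missing mandatory column(s): ", paste(need, collapse = ", "))
  x <- x[canon]
  x$snp_id <- as.character(x$snp_id)
  x$chrom <- as.character(x$chrom)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n"))
    x[[col]] <- as.numeric(x[[col]])
  rownames(x) <- NULL

  problems <- validate_summary_rows(x)
  if (nrow(x) == 0L)
    stop("summary table for '", trait_id, "' is empty (non-empty required)")
  if (length(problems))
    stop("invalid summary statistics for '", trait_id, "':\n  ",
         paste(problems, collapse = "\n  "))

  structure(x, trait_id = trait_id, pre_harmonized = isTRUE(pre_harmonized),
            class = c("summary_table", "data.frame"))
}

# Row-level validation; returns a character vector of problems, each
# naming the offending row indices. Total: every malformed row reported.
validate_summary_rows <- function(x) {
  problems <- character()
  bad <- function(idx, what) {
    if (any(idx)) sprintf("%s (row %s)", what,
                          paste(which(idx), collapse = ", "))
  }
  nuc <- c("A", "C", "G", "T")
  problems <- c(
    problems,
    bad(is.na(x$snp_id) | x$snp_id == "", "missing snp_id"),
    bad(duplicated(x$snp_id), "duplicate snp_id"),
    bad(!x$effect_allele %in% nuc,
        "effect_allele not a single A/C/G/T base"),
    bad(!x$other_allele %in% nuc,
        "other_allele not a single A/C/G/T base"),
    bad(x$effect_allele %in% nuc & x$effect_allele == x$other_allele,
        "effect_allele equals other_allele"),
    bad(is.na(x$beta), "missing beta"),
    bad(is.na(x$se) | x$se <= 0, "se not strictly positive"),
    bad(is.na(x$pval) | x$pval <= 0 | x$pval > 1, "pval outside (0, 1]"),
    bad(!is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1), "eaf outside (0, 1)"),
    bad(!is.na(x$n) & x$n < 2, "n below 2")
  )
  problems[!vapply(problems, is.null, logical(1))]
}

#' @export
print.summary_table <- function(x, ...) {
  cat("GWAS summary table: trait '", attr(x, "trait_id"), "', ",
      nrow(x), " SNPs", if (isTRUE(attr(x, "pre_harmonized")))
        " (pre-harmonized)", "\n", sep = "")
  print.data.frame(head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

#' Trait identifier of a summary table
#' @param x a [summary_table()].
#' @return Character scalar.
#' @export
trait_id <- function(x) attr(x, "trait_id")

#' Column dialects for summary-statistic files
#'
#' The canonical on-disk dialect is COJO-style whitespace/tab-delimited
#' text with header `SNP A1 A2 freq b se p N`. `dialect_cojo()` returns
#' that mapping; pass a modified copy (canonical field -> file column
#' name) to [read_summary_stats()] to adapt other headers. `beta`, `se`
#' and `pval` plus identifiers/alleles are mandatory; `eaf`, `n` and
#' `chrom` entries may point at absent columns, which read as `NA`.
#'
#' @param ... named overrides, e.g. `beta = "Effect"`, `pval = "P"`.
#' @return Named character vector mapping canonical fields to columns.
#' @examples
#' dialect_cojo(pval = "P-value")
#' @export
dialect_cojo <- function(...) {
  d <- c(snp_id = "SNP", effect_allele = "A1", other_allele = "A2",
         eaf = "freq", beta = "b", se = "se", pval = "p", n = "N",
         chrom = "chrom")
  over <- c(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(d))
    if (length(unknown))
      stop("unknown dialect field(s): ", paste(unknown, collapse = ", "))
    d[names(over)] <- over
  }
  d
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads whitespace- or tab-delimited summary statistics, maps the header
#' onto the canonical fields through `dialect`, and validates every row
#' against the `summary_table` invariants (positive SEs, p-values in
#' (0, 1], biallelic single-base alleles, unique SNP ids). Missing `eaf`
#' or `n` values are encoded as `NA`.
#'
#' @param path file to read.
#' @param dialect canonical-field to column-name mapping, see
#'   [dialect_cojo()].
#' @param trait_id trait name; defaults to the file name without
#'   extension.
#' @param pre_harmonized passed to [summary_table()].
#' @return A [summary_table()]; row order of the file is preserved.
#' @examples
#' f <- system.file("extdata", "oxoproline_exposure.tsv",
#'                  package = "metamr")
#' tab <- read_summary_stats(f, trait_id = "5-oxoproline")
#' head(tab$snp_id)
#' @export
read_summary_stats <- function(path, dialect = dialect_cojo(),
                               trait_id = NULL, pre_harmonized = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "",
                           na.strings = c("NA", "."), colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  mandatory <- c("snp_id", "effect_allele", "other_allele",
                 "beta", "se", "pval")
  miss <- mandatory[!dialect[mandatory] %in% names(raw)]
  if (length(miss))
    stop("missing mandatory column(s): ",
         paste(sprintf("%s (expected header '%s')", miss, dialect[miss]),
               collapse = ", "))
  pick <- function(field)
    if (dialect[[field]] %in% names(raw)) raw[[dialect[[field]]]]
    else rep(NA, nrow(raw))
  out <- data.frame(snp_id = pick("snp_id"), chrom = pick("chrom"),
                    effect_allele = pick("effect_allele"),
                    other_allele = pick("other_allele"),
                    eaf = pick("eaf"), beta = pick("beta"), se = pick("se"),
                    pval = pick("pval"), n = pick("n"),
                    stringsAsFactors = FALSE)
  summary_table(out, trait_id %||% sub("\\.[^.]*$", "", basename(path)),
                pre_harmonized = pre_harmonized)
}

#' Write a summary table back to the canonical dialect
#'
#' @param x a [summary_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  stopifnot(inherits(x, "summary_table"))
  out <- data.frame(SNP = x$snp_id, A1 = x$effect_allele,
                    A2 = x$other_allele, freq = fmt_num(x$eaf),
                    b = fmt_num(x$beta), se = fmt_num(x$se),
                    p = fmt_num(x$pval), N = fmt_num(x$n),
                    chrom = x$chrom, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# numbers at >= 10 significant digits so round-trips hold at 6
fmt_num <- function(x) ifelse(is.na(x), NA, formatC(x, digits = 10,
                                                    format = "g"))

#' Write and re-read causal-effect results
#'
#' Serializes a collection of MR results to tab-delimited text with the
#' fixed column order `trait, method, beta, se, ci_low, ci_high, pval,
#' n_snps` (any further columns follow). Numbers are written with enough
#' digits that reading the file back reproduces them to at least 6
#' significant digits.
#'
#' @param results a data frame of results (e.g. from
#'   [as.data.frame.mr_fit()] or [screen_exposures()]), or a list of
#'   [mr_result] objects.
#' @param path output file.
#' @return `path` invisibly for `write_results()`; a data frame for
#'   `read_results()`.
#' @examples
#' fx <- load_fixture("5-oxoproline")
#' fit <- mr_fit(fx$exposure, fx$outcome, methods = "ivw")
#' tf <- tempfile(fileext = ".tsv")
#' write_results(as.data.frame(fit), tf)
#' read_results(tf)
#' @export
write_results <- function(results, path) {
  if (inherits(results, "mr_result")) results <- list(results)
  if (is.list(results) && !is.data.frame(results) &&
      all(vapply(results, inherits, logical(1), "mr_result")))
    results <- do.call(rbind, lapply(results, as.data.frame))
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("results collection is empty; nothing to write")
  lead <- intersect(c("trait", "method", "beta", "se", "ci_low", "ci_high",
                      "pval", "n_snps"), names(results))
  results <- results[c(lead, setdiff(names(results), lead))]
  num <- vapply(results, is.numeric, logical(1))
  results[num] <- lapply(results[num], fmt_num)
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, na.strings = "NA", stringsAsFactors = FALSE)
}
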