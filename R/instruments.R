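#' Pairwise linkage-disequilibrium tables
#'
#' A sparse pairwise r-squared map plus variant positions, the inputs
#' greedy clumping needs. Pairs absent from the table are taken as
#' r^2 = 0 (a variant with itself is 1); the map is symmetric. Positions
#' are base-pair coordinates per chromosome; variants without a position
#' are treated by [clump_greedy()] as sitting alone on their own
#' pseudo-chromosome.
#'
#' @param r2 data frame with columns `snp_a`, `snp_b`, `r2` (values in
#'   \[0, 1\]).
#' @param positions optional data frame with columns `snp_id`, `chrom`,
#'   `bp`.
#' @return An object of class `ld_table`.
#' @examples
#' ld <- ld_table(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.5),
#'                data.frame(snp_id = c("rs1", "rs2"), chrom = "1",
#'                           bp = c(1000, 2000)))
#' @export
ld_table <- function(r2 = NULL, positions = NULL) {
  if (is.null(r2))
    r2 <- data.frame(snp_a = character(), snp_b = character(),
                     r2 = numeric(), stringsAsFactors = FALSE)
  stopifnot(is.data.frame(r2),
            all(c("snp_a", "snp_b", "r2") %in% names(r2)))
  r2$r2 <- as.numeric(r2$r2)
  if (any(is.na(r2$r2)) || any(r2$r2 < 0) || any(r2$r2 > 1))
    stop("r2 values must lie in [0, 1]")
  if (!is.null(positions)) {
    stopifnot(is.data.frame(positions),
              all(c("snp_id", "chrom", "bp") %in% names(positions)))
    positions$snp_id <- as.character(positions$snp_id)
    positions$chrom <- as.character(positions$chrom)
    positions$bp <- as.numeric(positions$bp)
    if (anyDuplicated(positions$snp_id))
      stop("duplicate snp_id in positions")
  }
  structure(list(r2 = r2, positions = positions), class = "ld_table")
}

#' @rdname ld_table
#' @param r2_path TSV with header `snp_a snp_b r2`.
#' @param positions_path optional TSV with header `snp_id chrom bp`.
#' @export
read_ld_table <- function(r2_path, positions_path = NULL) {
  r2 <- utils::read.delim(r2_path, stringsAsFactors = FALSE)
  pos <- if (!is.null(positions_path))
    utils::read.delim(positions_path, stringsAsFactors = FALSE)
  ld_table(r2, pos)
}

# symmetric sparse lookup of r2 between one SNP and a set of SNPs
ld_r2 <- function(ld, a, b) {
  out <- numeric(length(b))
  out[b == a] <- 1
  hit <- (ld$r2$snp_a == a & ld$r2$snp_b %in% b) |
         (ld$r2$snp_b == a & ld$r2$snp_a %in% b)
  for (i in which(hit)) {
    other <- if (ld$r2$snp_a[i] == a) ld$r2$snp_b[i] else ld$r2$snp_a[i]
    out[b == other] <- pmax(out[b == other], ld$r2$r2[i])
  }
  out
}

#' Select instruments by association p-value
#'
#' Retains exactly the records with `pval` strictly below `threshold`
#' (the genome-wide suggestive cut used for metabolite instruments is
#' 1e-5), preserving row order. An empty result is allowed and flagged
#' with a warning.
#'
#' @param table a [summary_table()].
#' @param threshold probability; strict `<` is applied.
#' @return The filtered [summary_table()].
#' @export
select_by_pvalue <- function(table, threshold = 1e-5) {
  stopifnot(inherits(table, "summary_table"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1)
  keep <- table$pval < threshold
  if (!any(keep))
    warning("no records pass p < ", format(threshold), " for trait '",
            trait_id(table), "'")
  subset_summary_table(table, keep)
}

# subset rows of a summary_table, preserving class and attributes
subset_summary_table <- function(table, keep) {
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, trait_id = trait_id(table),
            pre_harmonized = isTRUE(attr(table, "pre_harmonized")),
            class = c("summary_table", "data.frame"))
}

#' Greedy LD clumping of candidate instruments
#'
#' Reproduces the index-SNP selection normally delegated to PLINK:
#' candidates are visited in order of ascending p-value (ties broken by
#' lexicographic `snp_id`); a candidate is kept unless it lies within
#' `window_kb` of an already-kept SNP on the same chromosome *and* its
#' r-squared with that SNP is at least `r2_threshold`. The defaults
#' r^2 < 0.1 within 500 kb match the instrument-selection protocol of
#' the worked example. Output rows keep their original table order.
#'
#' @param table a [summary_table()] of candidates.
#' @param ld an [ld_table()]; pairs absent from it count as r^2 = 0.
#' @param r2_threshold proportion in \[0, 1\].
#' @param window_kb window half-width in kilobases, non-negative.
#' @return The clumped [summary_table()]; attribute `"clumped_out"`
#'   lists the removed SNPs and the index SNP each was assigned to, and
#'   `"no_position"` any SNPs lacking coordinates (treated as their own
#'   chromosome).
#' @export
clump_greedy <- function(table, ld, r2_threshold = 0.1, window_kb = 500) {
  stopifnot(inherits(table, "summary_table"), inherits(ld, "ld_table"))
  if (!is.numeric(r2_threshold) || r2_threshold < 0 || r2_threshold > 1)
    stop("r2_threshold must lie in [0, 1]")
  if (!is.numeric(window_kb) || window_kb < 0)
    stop("window_kb must be non-negative")

  pos <- ld$positions
  idx <- match(table$snp_id, if (is.null(pos)) character() else pos$snp_id)
  chrom <- if (is.null(pos)) rep(NA_character_, nrow(table)) else pos$chrom[idx]
  bp <- if (is.null(pos)) rep(NA_real_, nrow(table)) else pos$bp[idx]
  nopos <- is.na(chrom) | is.na(bp)
  # unmapped SNPs can never be within a window of anything
  chrom[nopos] <- paste0(".nopos_", table$snp_id[nopos])
  bp[nopos] <- 0

  ord <- order(table$pval, table$snp_id)
  kept <- integer(0)
  out <- data.frame(snp_id = character(), index_snp = character(),
                    stringsAsFactors = FALSE)
  for (i in ord) {
    conflict <- NA_integer_
    for (k in kept) {
      if (chrom[k] == chrom[i] &&
          abs(bp[k] - bp[i]) <= window_kb * 1000 &&
          ld_r2(ld, table$snp_id[i], table$snp_id[k]) >= r2_threshold) {
        conflict <- k
        break
      }
    }
    if (is.na(conflict)) kept <- c(kept, i)
    else out <- rbind(out, data.frame(snp_id = table$snp_id[i],
                                      index_snp = table$snp_id[conflict],
                                      stringsAsFactors = FALSE))
  }
  res <- subset_summary_table(table, sort(kept))
  attr(res, "clumped_out") <- out
  attr(res, "no_position") <- table$snp_id[nopos]
  res
}

#' Instrument strength from summary statistics
#'
#' Per-SNP variance explained and F statistic computed from the printed
#' columns alone: with `z = beta/se` and GWAS sample size `n`,
#' `R^2 = z^2 / (z^2 + n - 2)` and `F = (n - 2) R^2 / (1 - R^2)`, which
#' algebraically equals `z^2`. This is the standard summary-level
#' approximation; it needs no allele frequencies. `F > 10` is the
#' conventional adequacy bar for instruments.
#'
#' @param table a [summary_table()].
#' @param n_override sample size used where a record's `n` is missing
#'   (e.g. 7824 for the metabolomics GWAS behind the bundled fixture).
#' @return An object of class `strength_report`: per-SNP `r2` and `f`
#'   plus `total_r2`, `min_f`, `mean_f`.
#' @examples
#' fx <- load_fixture("5-oxoproline")
#' rep <- instrument_strength(fx$exposure, n_override = 7824)
#' rep$min_f
#' @export
instrument_strength <- function(table, n_override = NULL) {
  stopifnot(inherits(table, "summary_table"))
  n <- table$n
  if (!is.null(n_override)) n[is.na(n)] <- n_override
  if (any(is.na(n)))
    stop("sample size required for strength statistics: per-SNP n is ",
         "missing and no n_override was given")
  if (any(n <= 2)) stop("sample sizes must exceed 2")
  z <- table$beta / table$se
  r2 <- z^2 / (z^2 + n - 2)
  f <- (n - 2) * r2 / (1 - r2)
  structure(list(snp_id = table$snp_id, r2 = r2, f = f,
                 total_r2 = sum(r2), min_f = min(f), mean_f = mean(f)),
            class = "strength_report")
}

#' @export
print.strength_report <- function(x, ...) {
  cat("Instrument strength over", length(x$snp_id), "SNPs\n")
  cat(sprintf("  total R2 %.4f | F: min %.2f, mean %.2f\n",
              x$total_r2, x$min_f, x$mean_f))
  invisible(x)
}

#' Drop weak instruments
#'
#' Retains SNPs whose F statistic is strictly greater than `f_min`
#' (strict, so `F = 10` exactly is dropped under the default bar).
#'
#' @param table a [summary_table()].
#' @param report matching [instrument_strength()] output.
#' @param f_min threshold, default 10.
#' @return The filtered [summary_table()].
#' @export
filter_weak <- function(table, report, f_min = 10) {
  stopifnot(inherits(table, "summary_table"),
            inherits(report, "strength_report"))
  if (!identical(report$snp_id, table$snp_id))
    stop("strength report is not aligned with the table")
  subset_summary_table(table, report$f > f_min)
}
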