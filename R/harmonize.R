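#' Harmonized instrument sets
#'
#' An `instrument_set` holds, for one exposure-outcome test, the per-SNP
#' quadruples all estimators consume: exposure effects `beta_x` with
#' standard errors `se_x` and outcome effects `beta_y` with `se_y`,
#' every effect expressed on the same effect allele. `J` is the number
#' of instruments.
#'
#' @param exposure_id,outcome_id trait labels.
#' @param snp_ids character vector of unique variant ids.
#' @param beta_x,se_x,beta_y,se_y numeric vectors, same length as
#'   `snp_ids`; both SE vectors strictly positive.
#' @return An object of class `instrument_set`.
#' @examples
#' instrument_set("exposure", "outcome", c("rs1", "rs2", "rs3"),
#'                beta_x = c(0.1, 0.12, 0.08), se_x = rep(0.01, 3),
#'                beta_y = c(0.03, 0.04, 0.02), se_y = rep(0.01, 3))
#' @export
instrument_set <- function(exposure_id, outcome_id, snp_ids,
                           beta_x, se_x, beta_y, se_y) {
  snp_ids <- as.character(snp_ids)
  J <- length(snp_ids)
  if (J < 1L) stop("instrument set must contain at least one SNP")
  lens <- c(length(beta_x), length(se_x), length(beta_y), length(se_y))
  if (any(lens != J))
    stop("beta/se vectors must all have length ", J)
  if (anyDuplicated(snp_ids))
    stop("duplicate snp_ids in instrument set: ",
         paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  if (any(!is.finite(se_x)) || any(se_x <= 0) ||
      any(!is.finite(se_y)) || any(se_y <= 0))
    stop("standard errors must be strictly positive and finite")
  if (any(!is.finite(beta_x)) || any(!is.finite(beta_y)))
    stop("effect estimates must be finite")
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 snp_ids = snp_ids,
                 beta_x = as.numeric(beta_x), se_x = as.numeric(se_x),
                 beta_y = as.numeric(beta_y), se_y = as.numeric(se_y),
                 J = J),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set: ", x$exposure_id, " -> ", x$outcome_id,
      " (J = ", x$J, ")\n", sep = "")
  print.data.frame(head(as.data.frame(x), 6L))
  if (x$J > 6L) cat("... (", x$J - 6L, " more SNPs)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.instrument_set <- function(x, ...) {
  data.frame(snp_id = x$snp_ids, beta_x = x$beta_x, se_x = x$se_x,
             beta_y = x$beta_y, se_y = x$se_y, stringsAsFactors = FALSE)
}

# subset an instrument set by index, keeping metadata
instrument_subset <- function(x, idx) {
  instrument_set(x$exposure_id, x$outcome_id, x$snp_ids[idx],
                 x$beta_x[idx], x$se_x[idx], x$beta_y[idx], x$se_y[idx])
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) DNA_COMPLEMENT[a1] == a2

#' Align exposure and outcome summary statistics on a common allele
#'
#' For every SNP shared between the two tables the outcome record is
#' re-expressed on the exposure's effect allele. Allele pairs reported
#' in swapped order flip the sign of the outcome beta; strand-flip
#' complements (A<->T, C<->G on the opposite strand) are resolved before
#' comparison; irreconcilable allele pairs are excluded. Palindromic
#' SNPs (A/T or C/G), whose strand cannot be inferred from the alleles
#' alone, follow `palindromic_policy`:
#'
#' * `"drop"` (default): always excluded, reason `"palindromic"`.
#' * `"keep_if_eaf"`: kept when both allele frequencies are present,
#'   both are further than `eaf_tolerance` from 0.5, and the minor-allele
#'   frequencies agree within `eaf_tolerance` under the inferred
#'   orientation (same side of 0.5 keeps the reported sign, opposite
#'   sides flip it); otherwise excluded.
#'
#' If both tables carry the `pre_harmonized` flag (bundled transcribed
#' instrument tables do), rows are paired by `snp_id` with no allele
#' arithmetic.
#'
#' @param exposure,outcome [summary_table()] objects.
#' @param palindromic_policy `"drop"` or `"keep_if_eaf"`.
#' @param eaf_tolerance allele-frequency tolerance used by
#'   `"keep_if_eaf"`; default 0.08.
#' @return A list: `instruments` (an [instrument_set()]) and
#'   `exclusions` (data frame of `snp_id`, `reason`). The count of
#'   exclusions plus retained instruments equals the number of shared
#'   SNPs.
#' @examples
#' ex <- summary_table(data.frame(snp_id = "rs1", effect_allele = "A",
#'   other_allele = "G", beta = 0.1, se = 0.01, pval = 1e-9), "X")
#' ou <- summary_table(data.frame(snp_id = "rs1", effect_allele = "G",
#'   other_allele = "A", beta = -0.05, se = 0.01, pval = 1e-4), "Y")
#' harmonize_pair(ex, ou)$instruments$beta_y  # +0.05 after flip
#' @export
harmonize_pair <- function(exposure, outcome,
                           palindromic_policy = c("drop", "keep_if_eaf"),
                           eaf_tolerance = 0.08) {
  stopifnot(inherits(exposure, "summary_table"),
            inherits(outcome, "summary_table"))
  palindromic_policy <- match.arg(palindromic_policy)
  shared <- exposure$snp_id[exposure$snp_id %in% outcome$snp_id]
  if (length(shared) == 0L) stop("no shared instruments")

  ex <- exposure[match(shared, exposure$snp_id), ]
  ou <- outcome[match(shared, outcome$snp_id), ]

  if (isTRUE(attr(exposure, "pre_harmonized")) &&
      isTRUE(attr(outcome, "pre_harmonized"))) {
    return(list(
      instruments = instrument_set(trait_id(exposure), trait_id(outcome),
                                   shared, ex$beta, ex$se, ou$beta, ou$se),
      exclusions = data.frame(snp_id = character(), reason = character(),
                              stringsAsFactors = FALSE)))
  }

  flip <- rep(NA, length(shared))      # NA = excluded
  reason <- rep(NA_character_, length(shared))
  for (i in seq_along(shared)) {
    e1 <- ex$effect_allele[i]; o1 <- ex$other_allele[i]
    e2 <- ou$effect_allele[i]; o2 <- ou$other_allele[i]
    if (is_palindromic(e1, o1)) {
      if (!setequal(c(e2, o2), c(e1, o1))) { reason[i] <- "allele_mismatch"; next }
      if (palindromic_policy == "drop") { reason[i] <- "palindromic"; next }
      f1 <- ex$eaf[i]; f2 <- ou$eaf[i]
      if (is.na(f1) || is.na(f2) ||
          abs(f1 - 0.5) <= eaf_tolerance || abs(f2 - 0.5) <= eaf_tolerance) {
        reason[i] <- "palindromic"; next
      }
      if (abs(pmin(f1, 1 - f1) - pmin(f2, 1 - f2)) >= eaf_tolerance) {
        reason[i] <- "palindromic"; next
      }
      # same side of 0.5: reported effect allele is the same physical
      # allele on either strand; opposite sides: strands disagree, flip.
      flip[i] <- (f1 - 0.5) * (f2 - 0.5) < 0
      next
    }
    e2c <- DNA_COMPLEMENT[[e2]]; o2c <- DNA_COMPLEMENT[[o2]]
    if (e2 == e1 && o2 == o1) flip[i] <- FALSE
    else if (e2 == o1 && o2 == e1) flip[i] <- TRUE
    else if (e2c == e1 && o2c == o1) flip[i] <- FALSE
    else if (e2c == o1 && o2c == e1) flip[i] <- TRUE
    else reason[i] <- "allele_mismatch"
  }

  keep <- !is.na(flip)
  if (!any(keep)) stop("no shared instruments survive harmonization")
  beta_y <- ifelse(flip[keep], -ou$beta[keep], ou$beta[keep])
  list(instruments = instrument_set(trait_id(exposure), trait_id(outcome),
                                    shared[keep], ex$beta[keep], ex$se[keep],
                                    beta_y, ou$se[keep]),
       exclusions = data.frame(snp_id = shared[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE))
}

#' Orient instruments to positive exposure effects
#'
#' Sign-flips `beta_x` and `beta_y` together for every SNP with a
#' negative exposure effect, so all `beta_x >= 0`. Wald ratios are
#' unchanged; MR-Egger requires this orientation and applies it
#' internally.
#'
#' @param instruments an [instrument_set()].
#' @return The re-oriented [instrument_set()].
#' @examples
#' x <- instrument_set("X", "Y", c("a", "b"), c(-0.062, 0.01),
#'                     c(0.003, 0.002), c(-0.0196, 0.001), c(0.004, 0.003))
#' orient_positive(x)$beta_x
#' @export
orient_positive <- function(instruments) {
  stopifnot(inherits(instruments, "instrument_set"))
  s <- ifelse(instruments$beta_x < 0, -1, 1)
  instruments$beta_x <- s * instruments$beta_x
  instruments$beta_y <- s * instruments$beta_y
  instruments
}
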