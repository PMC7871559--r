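#' Cochran Q heterogeneity test across instruments
#'
#' Measures dispersion of the per-SNP Wald ratios about the fixed-effect
#' IVW estimate: with ratios `r_j = by_j/bx_j` and weights
#' `w_j = bx_j^2/sy_j^2`, `Q = sum(w_j (r_j - theta_IVW)^2)` on `J - 1`
#' degrees of freedom, with an upper-tail chi-square p-value.
#' `I^2 = max(0, (Q - df)/Q)` expresses the share of variability beyond
#' chance; by convention `I^2 > 25%` or a Q p-value below 0.05 is read
#' as a heterogeneity (possible pleiotropy) signal.
#'
#' @param instruments an [instrument_set()] with at least 2 SNPs and no
#'   zero exposure effect.
#' @return An object of class `heterogeneity_report`: `q`, `df`, `pval`,
#'   `i2` (proportion in \[0, 1)).
#' @examples
#' fx <- load_fixture("5-oxoproline")
#' x <- harmonize_pair(fx$exposure, fx$outcome)$instruments
#' cochran_q(x)$i2  # about 0.30
#' @export
cochran_q <- function(instruments) {
  stopifnot(inherits(instruments, "instrument_set"))
  J <- instruments$J
  if (J < 2L) stop("Cochran Q requires at least 2 instruments")
  bx <- instruments$beta_x; by <- instruments$beta_y
  sy <- instruments$se_y
  if (any(bx == 0)) stop("undefined Wald ratio: exposure effect is zero")
  w <- bx^2 / sy^2
  theta <- mr_ivw(instruments)$beta
  q <- sum(w * (by / bx - theta)^2)
  df <- J - 1
  structure(list(q = q, df = df,
                 pval = max(pchisq(q, df, lower.tail = FALSE),
                            .Machine$double.xmin),
                 i2 = if (q == 0) 0 else max(0, (q - df) / q)),
            class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat(sprintf("Cochran Q %.3f on %d df, p %.3g; I2 %.1f%%\n",
              x$q, x$df, x$pval, 100 * x$i2))
  invisible(x)
}

#' Pleiotropy and heterogeneity flags
#'
#' Collects the standard warning signals into a named flag set:
#' `i2_above_cut` (I^2 strictly above `i2_cut`), `heterogeneity_p`
#' (Q p below `p_cut`), `egger_intercept_p` and `presso_global_p`
#' (respective tests below `p_cut`). Flags are reportable evidence,
#' not a verdict: downstream tiering annotates them without vetoing an
#' association.
#'
#' @param het a [cochran_q()] report.
#' @param egger_intercept_p,presso_global_p test p-values (`NA` skips
#'   the corresponding flag).
#' @param i2_cut strict threshold on I^2, default 0.25.
#' @param p_cut threshold on p-values, default 0.05.
#' @return Character vector of raised flags (possibly empty).
#' @export
pleiotropy_flags <- function(het, egger_intercept_p = NA,
                             presso_global_p = NA,
                             i2_cut = 0.25, p_cut = 0.05) {
  stopifnot(inherits(het, "heterogeneity_report"))
  flags <- c(
    if (het$i2 > i2_cut) "i2_above_cut",
    if (het$pval < p_cut) "heterogeneity_p",
    if (!is.na(egger_intercept_p) && egger_intercept_p < p_cut)
      "egger_intercept_p",
    if (!is.na(presso_global_p) && presso_global_p < p_cut)
      "presso_global_p")
  flags %||% character()
}

#' Funnel-plot data
#'
#' Plot-ready per-SNP table of Wald ratio against precision (inverse
#' first-order ratio SE). Symmetry of the funnel about the combined
#' estimate is the usual visual check for directional pleiotropy; no
#' rendering is done here (see [plot.mr_fit()]).
#'
#' @param instruments an [instrument_set()].
#' @return Data frame with columns `snp_id`, `ratio`, `precision`.
#' @export
funnel_data <- function(instruments) {
  stopifnot(inherits(instruments, "instrument_set"))
  bx <- instruments$beta_x
  if (any(bx == 0)) stop("undefined Wald ratio: exposure effect is zero")
  data.frame(snp_id = instruments$snp_ids,
             ratio = instruments$beta_y / bx,
             precision = abs(bx) / instruments$se_y,
             stringsAsFactors = FALSE)
}
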