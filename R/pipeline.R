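#' Bonferroni significance threshold
#'
#' `alpha / m` for `m` exposures tested against one outcome; with the
#' full metabolome panel (`m = 486`) and `alpha = 0.05` this is the
#' 1.03e-4 bar used to declare a causal association, while `p < alpha`
#' short of it is reported as suggestive.
#'
#' @param alpha family-wise level, default 0.05.
#' @param m number of exposures, at least 1.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 486)
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1)
    stop("m must be a count of at least 1")
  stopifnot(alpha > 0, alpha <= 1)
  alpha / m
}

#' Screening configuration
#'
#' Bundles every tunable threshold of the screening pipeline. Defaults
#' reproduce the discovery protocol of the worked example: instrument
#' p < 1e-5, clumping at r^2 < 0.1 within 500 kb, F > 10, palindromic
#' SNPs dropped, fixed-effect IVW as primary model, Bonferroni tiering
#' at `alpha = 0.05` over the number of exposures supplied (`m`
#' overrides it, e.g. `m = 486` to apply the metabolome-wide bar to a
#' fixture subset).
#'
#' @param p_threshold instrument selection p-value cut.
#' @param clump_r2,clump_kb greedy clumping thresholds.
#' @param f_min strength bar (strict `F >` retained).
#' @param n_exposure exposure GWAS sample size used where per-SNP `n`
#'   is missing; `NULL` skips the strength filter for such tables (the
#'   skip is recorded in the screen row notes).
#' @param palindromic_policy,eaf_tolerance see [harmonize_pair()].
#' @param alpha,m tiering parameters, see [bonferroni_threshold()].
#' @param model IVW model, `"fixed"` or `"multiplicative_re"`.
#' @param n_boot weighted-median bootstrap replicates.
#' @param presso_n_sim MR-PRESSO simulation replicates.
#' @param seed base seed; exposure `i` runs under `seed + i` so reruns
#'   are bit-identical.
#' @return An object of class `mr_config`.
#' @export
mr_config <- function(p_threshold = 1e-5, clump_r2 = 0.1, clump_kb = 500,
                      f_min = 10, n_exposure = NULL,
                      palindromic_policy = c("drop", "keep_if_eaf"),
                      eaf_tolerance = 0.08, alpha = 0.05, m = NULL,
                      model = c("fixed", "multiplicative_re"),
                      n_boot = 1000, presso_n_sim = 1000, seed = NULL) {
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_kb = clump_kb, f_min = f_min,
                 n_exposure = n_exposure,
                 palindromic_policy = match.arg(palindromic_policy),
                 eaf_tolerance = eaf_tolerance, alpha = alpha, m = m,
                 model = match.arg(model), n_boot = n_boot,
                 presso_n_sim = presso_n_sim, seed = seed),
            class = "mr_config")
}

# run the full estimator battery on one harmonized instrument set;
# methods whose instrument minimum is not met yield NA plus a note.
run_estimators <- function(x, config, seed) {
  notes <- character()
  out <- list(ivw = NULL, egger = NULL, wm = NULL, presso = NULL,
              het = NULL)
  out$ivw <- mr_ivw(x, model = config$model)
  if (x$J >= 3L) {
    out$egger <- mr_egger(x)
    out$wm <- weighted_median(x, n_boot = config$n_boot, seed = seed)
  } else notes <- c(notes, "egger:insufficient_instruments",
                    "weighted_median:insufficient_instruments")
  if (x$J >= 4L)
    out$presso <- mr_presso(x, n_sim = config$presso_n_sim,
                            seed = if (is.null(seed)) NULL else seed + 1L)
  else notes <- c(notes, "presso:insufficient_instruments")
  if (x$J >= 2L) out$het <- cochran_q(x)
  else notes <- c(notes, "heterogeneity:insufficient_instruments")
  out$notes <- notes
  out
}

# the PRESSO estimate a practitioner reports: outlier-corrected when
# outliers were flagged, otherwise the raw (= IVW) estimate
presso_reported <- function(p) {
  if (length(p$outlier_indices)) p$corrected else p$raw
}

#' Metabolome-wide causal screen
#'
#' Runs the full discovery workflow for each exposure against one
#' outcome: p-value selection, optional LD clumping, strength
#' filtering, harmonization, the four estimators, heterogeneity
#' diagnostics, pleiotropy flags, Bonferroni tiering and the
#' sensitivity robustness gate. Exposures whose instrument count falls
#' below a method's minimum are reported with
#' `"<method>:insufficient_instruments"` notes rather than dropped, so
#' the output always has one row per exposure.
#'
#' @param exposures named list of [summary_table()] objects (names
#'   default to each table's trait id).
#' @param outcome outcome [summary_table()].
#' @param ld optional [ld_table()]; without it clumping is skipped
#'   (appropriate when instruments are already independent).
#' @param config an [mr_config()].
#' @return A data frame of class `mr_screen`, one row per exposure:
#'   IVW (`beta_ivw`, `se_ivw`, `ci_low`, `ci_high`, `pval_ivw`),
#'   sensitivity estimates and p-values, Egger intercept p, PRESSO
#'   global p, `q`/`q_pval`/`i2`, comma-joined `flags` and `notes`,
#'   `tier` (`bonferroni_significant`, `suggestive` or `null`) and
#'   `robust`. Attribute `"details"` keeps the per-exposure objects,
#'   `"config"` the effective configuration and Bonferroni threshold.
#' @examples
#' fx <- load_fixture("5-oxoproline")
#' scr <- screen_exposures(list(fx$exposure), fx$outcome,
#'                         config = mr_config(m = 486, seed = 1,
#'                                            n_exposure = 7824))
#' scr$tier
#' @export
screen_exposures <- function(exposures, outcome, ld = NULL,
                             config = mr_config()) {
  if (!is.list(exposures) || length(exposures) == 0L ||
      !all(vapply(exposures, inherits, logical(1), "summary_table")))
    stop("exposures must be a non-empty list of summary tables")
  if (!inherits(outcome, "summary_table"))
    stop("outcome is not a valid summary table")
  ids <- names(exposures) %||% rep("", length(exposures))
  blank <- !nzchar(ids)
  ids[blank] <- vapply(exposures[blank], trait_id, character(1))
  m <- config$m %||% length(exposures)
  thr <- bonferroni_threshold(config$alpha, m)

  details <- vector("list", length(exposures))
  rows <- vector("list", length(exposures))
  for (i in seq_along(exposures)) {
    seed_i <- if (is.null(config$seed)) NULL else config$seed + i
    notes <- character()
    sel <- suppressWarnings(select_by_pvalue(exposures[[i]],
                                             config$p_threshold))
    if (!is.null(ld) && nrow(sel) > 0L)
      sel <- clump_greedy(sel, ld, config$clump_r2, config$clump_kb)
    if (nrow(sel) > 0L) {
      if (all(is.na(sel$n)) && is.null(config$n_exposure)) {
        notes <- c(notes, "strength_not_assessed")
      } else {
        sel <- filter_weak(sel, instrument_strength(sel, config$n_exposure),
                           config$f_min)
      }
    }
    if (nrow(sel) == 0L) {
      notes <- c(notes, "no_instruments")
      rows[[i]] <- screen_row_empty(ids[i], notes)
      next
    }
    h <- harmonize_pair(sel, outcome, config$palindromic_policy,
                        config$eaf_tolerance)
    est <- run_estimators(h$instruments, config, seed_i)
    notes <- c(notes, est$notes)
    flags <- if (!is.null(est$het))
      pleiotropy_flags(est$het,
                       if (!is.null(est$egger)) est$egger$intercept$pval
                       else NA,
                       if (!is.null(est$presso)) est$presso$global_pval
                       else NA)
    else character()
    tier <- if (est$ivw$pval < thr) "bonferroni_significant"
            else if (est$ivw$pval < config$alpha) "suggestive" else "null"
    pre <- if (!is.null(est$presso)) presso_reported(est$presso)
    row <- data.frame(
      exposure_id = ids[i], n_snps = h$instruments$J,
      beta_ivw = est$ivw$beta, se_ivw = est$ivw$se,
      ci_low = est$ivw$ci_low, ci_high = est$ivw$ci_high,
      pval_ivw = est$ivw$pval,
      egger_beta = est$egger$slope$beta %||% NA_real_,
      egger_pval = est$egger$slope$pval %||% NA_real_,
      egger_intercept_pval = est$egger$intercept$pval %||% NA_real_,
      wm_beta = est$wm$beta %||% NA_real_,
      wm_pval = est$wm$pval %||% NA_real_,
      presso_beta = pre$beta %||% NA_real_,
      presso_pval = pre$pval %||% NA_real_,
      presso_global_pval = est$presso$global_pval %||% NA_real_,
      q = est$het$q %||% NA_real_, q_pval = est$het$pval %||% NA_real_,
      i2 = est$het$i2 %||% NA_real_,
      flags = paste(flags, collapse = ","),
      notes = paste(notes, collapse = ","),
      tier = tier, stringsAsFactors = FALSE)
    row$robust <- robustness_gate(row)
    rows[[i]] <- row
    details[[i]] <- c(est, list(instruments = h$instruments,
                                exclusions = h$exclusions))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, details = setNames(details, ids),
            config = config, bonferroni = thr,
            class = c("mr_screen", "data.frame"))
}

screen_row_empty <- function(id, notes) {
  data.frame(exposure_id = id, n_snps = 0L, beta_ivw = NA_real_,
             se_ivw = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             pval_ivw = NA_real_, egger_beta = NA_real_,
             egger_pval = NA_real_, egger_intercept_pval = NA_real_,
             wm_beta = NA_real_, wm_pval = NA_real_,
             presso_beta = NA_real_, presso_pval = NA_real_,
             presso_global_pval = NA_real_, q = NA_real_,
             q_pval = NA_real_, i2 = NA_real_, flags = "",
             notes = paste(notes, collapse = ","), tier = NA_character_,
             robust = FALSE, stringsAsFactors = FALSE)
}

#' Sensitivity-based robustness gate
#'
#' An association is called robust when all three sensitivity
#' estimators (MR-Egger slope, weighted median, MR-PRESSO) reach
#' `p < p_cut` *and* their effect signs agree with the IVW sign.
#' Pleiotropy flags are reported alongside but do not veto. Missing
#' sensitivity results (insufficient instruments) fail the gate.
#'
#' @param row one row of a [screen_exposures()] result (or any list
#'   with fields `beta_ivw`, `egger_beta`, `egger_pval`, `wm_beta`,
#'   `wm_pval`, `presso_beta`, `presso_pval`).
#' @param p_cut sensitivity significance bar, default 0.05.
#' @return Logical.
#' @export
robustness_gate <- function(row, p_cut = 0.05) {
  betas <- c(row$egger_beta, row$wm_beta, row$presso_beta)
  ps <- c(row$egger_pval, row$wm_pval, row$presso_pval)
  if (any(is.na(betas)) || any(is.na(ps)) || is.na(row$beta_ivw))
    return(FALSE)
  all(ps < p_cut) && all(sign(betas) == sign(row$beta_ivw))
}

#' Replicate discovery estimates against alternative outcome GWAS
#'
#' Takes the discovery-selected instruments for one exposure and
#' re-estimates the causal effect against each alternative outcome
#' (another intelligence GWAS, cognitive performance, educational
#' attainment, income, ...), re-harmonizing the same SNPs to each
#' outcome and running IVW, MR-Egger and the weighted median.
#' Instruments are deliberately *not* reselected per outcome. If fewer
#' than half the instruments are found in an alternative outcome the
#' row carries a warning marker.
#'
#' @param exposure_ivs [summary_table()] of the already-selected
#'   discovery instruments.
#' @param alt_outcomes named list of outcome [summary_table()] objects.
#' @param config an [mr_config()].
#' @return Data frame of class `mr_replication`: one row per outcome
#'   with instrument counts, the three estimates with CIs and p-values,
#'   and `warning` (`"low_instrument_overlap"` or `""`).
#' @export
mr_replicate <- function(exposure_ivs, alt_outcomes,
                         config = mr_config()) {
  stopifnot(inherits(exposure_ivs, "summary_table"))
  if (!is.list(alt_outcomes) || length(alt_outcomes) == 0L ||
      !all(vapply(alt_outcomes, inherits, logical(1), "summary_table")))
    stop("alt_outcomes must be a non-empty list of summary tables")
  ids <- names(alt_outcomes) %||% rep("", length(alt_outcomes))
  blank <- !nzchar(ids)
  ids[blank] <- vapply(alt_outcomes[blank], trait_id, character(1))

  rows <- lapply(seq_along(alt_outcomes), function(i) {
    outc <- alt_outcomes[[i]]
    found <- mean(exposure_ivs$snp_id %in% outc$snp_id)
    warn <- if (found < 0.5) "low_instrument_overlap" else ""
    h <- harmonize_pair(exposure_ivs, outc, config$palindromic_policy,
                        config$eaf_tolerance)
    x <- h$instruments
    ivw <- mr_ivw(x, model = config$model)
    egger <- if (x$J >= 3L) mr_egger(x)
    wm <- if (x$J >= 3L)
      weighted_median(x, n_boot = config$n_boot,
                      seed = if (is.null(config$seed)) NULL
                             else config$seed + i)
    data.frame(outcome_id = ids[i], n_snps = x$J, found_frac = found,
               beta_ivw = ivw$beta, ci_low = ivw$ci_low,
               ci_high = ivw$ci_high, pval_ivw = ivw$pval,
               egger_beta = egger$slope$beta %||% NA_real_,
               egger_pval = egger$slope$pval %||% NA_real_,
               wm_beta = wm$beta %||% NA_real_,
               wm_pval = wm$pval %||% NA_real_,
               warning = warn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("mr_replication", "data.frame"))
}
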