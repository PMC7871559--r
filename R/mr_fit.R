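#' Fit a two-sample Mendelian randomization model
#'
#' The package's main entry point: estimates the causal effect of one
#' exposure on one outcome from GWAS summary statistics, with the
#' fixed-effect inverse-variance weighted estimator as the primary
#' model and MR-Egger, the weighted median and MR-PRESSO as sensitivity
#' estimators, plus Cochran Q / I-squared heterogeneity and pleiotropy
#' flags.
#'
#' `exposure` may be a pair of [summary_table()] objects (instruments
#' are then selected by p-value, optionally clumped against `ld`,
#' strength-filtered when sample sizes are available, and harmonized to
#' the outcome) or an already-harmonized [instrument_set()] (then
#' `outcome` is ignored).
#'
#' @param exposure a [summary_table()] or an [instrument_set()].
#' @param outcome the outcome [summary_table()] (when `exposure` is a
#'   table).
#' @param methods subset of `c("ivw", "egger", "weighted_median",
#'   "presso")`; IVW is always fitted.
#' @param config an [mr_config()] carrying thresholds and seeds.
#' @param ld optional [ld_table()] for clumping.
#' @return An object of class `mr_fit` with components `instruments`,
#'   `ivw`, `egger` (slope + intercept), `wm`, `presso`, `het`,
#'   `flags`, `exclusions` and `config`. Methods: [print.mr_fit()],
#'   [summary.mr_fit()], [coef.mr_fit()], [confint.mr_fit()],
#'   [plot.mr_fit()], [residuals.mr_fit()], [as.data.frame.mr_fit()].
#' @examples
#' fx <- load_fixture("5-oxoproline")
#' fit <- mr_fit(fx$exposure, fx$outcome, config = mr_config(seed = 7))
#' fit
#' coef(fit)
#' @export
mr_fit <- function(exposure, outcome = NULL,
                   methods = c("ivw", "egger", "weighted_median",
                               "presso"),
                   config = mr_config(), ld = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  exclusions <- NULL
  if (inherits(exposure, "instrument_set")) {
    x <- exposure
  } else {
    stopifnot(inherits(exposure, "summary_table"),
              inherits(outcome, "summary_table"))
    sel <- suppressWarnings(select_by_pvalue(exposure, config$p_threshold))
    if (nrow(sel) == 0L)
      stop("no instruments pass p < ", format(config$p_threshold))
    if (!is.null(ld))
      sel <- clump_greedy(sel, ld, config$clump_r2, config$clump_kb)
    if (!all(is.na(sel$n)) || !is.null(config$n_exposure))
      sel <- filter_weak(sel, instrument_strength(sel, config$n_exposure),
                         config$f_min)
    h <- harmonize_pair(sel, outcome, config$palindromic_policy,
                        config$eaf_tolerance)
    x <- h$instruments
    exclusions <- h$exclusions
  }

  seed <- config$seed
  fit <- list(instruments = x, config = config, exclusions = exclusions,
              ivw = mr_ivw(x, model = config$model),
              egger = NULL, wm = NULL, presso = NULL, het = NULL)
  if ("egger" %in% methods && x$J >= 3L) fit$egger <- mr_egger(x)
  if ("weighted_median" %in% methods && x$J >= 3L)
    fit$wm <- weighted_median(x, n_boot = config$n_boot, seed = seed)
  if ("presso" %in% methods && x$J >= 4L)
    fit$presso <- mr_presso(x, n_sim = config$presso_n_sim,
                            seed = if (is.null(seed)) NULL else seed + 1L)
  if (x$J >= 2L) fit$het <- cochran_q(x)
  fit$flags <- if (!is.null(fit$het))
    pleiotropy_flags(fit$het,
                     fit$egger$intercept$pval %||% NA,
                     fit$presso$global_pval %||% NA)
  else character()
  structure(fit, class = "mr_fit")
}

# results present in a fit, as a list of mr_result
fit_results <- function(x) {
  out <- list(x$ivw)
  if (!is.null(x$egger)) out <- c(out, list(x$egger$slope,
                                            x$egger$intercept))
  if (!is.null(x$wm)) out <- c(out, list(x$wm))
  if (!is.null(x$presso)) out <- c(out, list(x$presso$raw,
                                             x$presso$corrected))
  out
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("Two-sample MR: ", x$instruments$exposure_id, " -> ",
      x$instruments$outcome_id, " (J = ", x$instruments$J, ")\n\n",
      sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, 4)
  print.data.frame(df, row.names = FALSE)
  if (!is.null(x$het))
    cat(sprintf("\nHeterogeneity: Q %.2f (df %d, p %.3g), I2 %.1f%%\n",
                x$het$q, x$het$df, x$het$pval, 100 * x$het$i2))
  if (!is.null(x$presso) && length(x$presso$outlier_indices))
    cat("MR-PRESSO outliers:",
        paste(x$instruments$snp_ids[x$presso$outlier_indices],
              collapse = ", "), "\n")
  cat("Pleiotropy flags:",
      if (length(x$flags)) paste(x$flags, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' @describeIn mr_fit one row per fitted estimator (`trait`, `method`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `pval`, `n_snps`).
#' @param x,object an `mr_fit`.
#' @param ... unused.
#' @export
as.data.frame.mr_fit <- function(x, ...) {
  out <- do.call(rbind, lapply(fit_results(x), as.data.frame))
  cbind(trait = x$instruments$exposure_id, out, stringsAsFactors = FALSE)
}

#' @describeIn mr_fit named vector of causal-effect estimates.
#' @export
coef.mr_fit <- function(object, ...) {
  res <- fit_results(object)
  setNames(vapply(res, `[[`, numeric(1), "beta"),
           vapply(res, `[[`, character(1), "method"))
}

#' @describeIn mr_fit 95% (or `level`) confidence bounds per estimator.
#'   Normal quantiles are used except MR-Egger, which is t-based on
#'   `J - 2` degrees of freedom.
#' @param parm ignored (all estimators are returned).
#' @param level confidence level.
#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  res <- fit_results(object)
  J <- object$instruments$J
  out <- t(vapply(res, function(r) {
    q <- if (startsWith(r$method, "egger")) qt((1 + level) / 2, J - 2)
         else qnorm((1 + level) / 2)
    c(r$beta - q * r$se, r$beta + q * r$se)
  }, numeric(2)))
  dimnames(out) <- list(vapply(res, `[[`, character(1), "method"),
                        sprintf("%.1f %%", 50 * (1 + c(-level, level))))
  out
}

#' @describeIn mr_fit residuals of the primary IVW fit in outcome-effect
#'   space (`beta_y - theta * beta_x`), optionally standardized by
#'   `se_y`.
#' @param type `"response"` or `"standardized"`.
#' @export
residuals.mr_fit <- function(object, type = c("response", "standardized"),
                             ...) {
  type <- match.arg(type)
  x <- object$instruments
  r <- x$beta_y - object$ivw$beta * x$beta_x
  if (type == "standardized") r <- r / x$se_y
  setNames(r, x$snp_ids)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  if (!is.null(f$egger))
    cat(sprintf("Egger intercept: %.4g (p %.3g) - directional pleiotropy test\n",
                f$egger$intercept$beta, f$egger$intercept$pval))
  if (!is.null(f$presso))
    cat(sprintf("MR-PRESSO global p: %.3g (n_sim %d), distortion p: %s\n",
                f$presso$global_pval, f$presso$n_sim,
                format(f$presso$distortion_pval, digits = 3)))
  if (!is.null(f$exclusions) && nrow(f$exclusions))
    cat("Harmonization exclusions:", nrow(f$exclusions), "SNP(s)\n")
  invisible(x)
}

#' Scatter and funnel plots for an MR fit
#'
#' `type = "scatter"` draws per-SNP outcome effects against exposure
#' effects (oriented to positive exposure effects) with the IVW line
#' through the origin and, if fitted, the MR-Egger line with its
#' intercept. `type = "funnel"` draws Wald ratios against precision
#' with a vertical line at the IVW estimate.
#'
#' @param x an [mr_fit()].
#' @param type `"scatter"` or `"funnel"`.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.mr_fit <- function(x, type = c("scatter", "funnel"), ...) {
  type <- match.arg(type)
  ins <- orient_positive(x$instruments)
  if (type == "scatter") {
    plot(ins$beta_x, ins$beta_y,
         xlab = "SNP effect on exposure",
         ylab = "SNP effect on outcome",
         main = paste(ins$exposure_id, "->", ins$outcome_id), ...)
    segments(ins$beta_x, ins$beta_y - 1.96 * ins$se_y,
             ins$beta_x, ins$beta_y + 1.96 * ins$se_y, col = "grey60")
    abline(0, x$ivw$beta, lwd = 2)
    if (!is.null(x$egger))
      abline(x$egger$intercept$beta, x$egger$slope$beta, lty = 2, lwd = 2)
  } else {
    fd <- funnel_data(ins)
    plot(fd$ratio, fd$precision, xlab = "Wald ratio",
         ylab = "precision (1 / ratio SE)",
         main = paste("Funnel:", ins$exposure_id), ...)
    abline(v = x$ivw$beta, lwd = 2)
  }
  invisible(x)
}
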