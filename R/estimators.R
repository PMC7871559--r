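#' Causal-effect estimate container
#'
#' One estimator's result: point estimate, standard error, 95% interval,
#' two-sided p-value and the number of instruments used. Created by the
#' estimator functions; rarely constructed by hand.
#'
#' @param method tag, one of `wald`, `ivw`, `egger_slope`,
#'   `egger_intercept`, `weighted_median`, `presso_raw`,
#'   `presso_corrected`.
#' @param beta,se estimate and standard error.
#' @param ci_low,ci_high 95% confidence bounds (must bracket `beta`).
#' @param pval two-sided p in (0, 1].
#' @param n_snps instruments used.
#' @return An object of class `mr_result`.
#' @export
mr_result <- function(method, beta, se, ci_low, ci_high, pval, n_snps) {
  stopifnot(is.character(method), length(method) == 1L,
            is.finite(beta), is.finite(se), se >= 0)
  if (!(ci_low <= beta && beta <= ci_high))
    stop("confidence interval does not bracket the estimate")
  if (!(pval > 0 && pval <= 1)) stop("pval outside (0, 1]")
  structure(list(method = method, beta = beta, se = se, ci_low = ci_low,
                 ci_high = ci_high, pval = pval, n_snps = n_snps),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: beta %.4g (95%% CI %.4g, %.4g), se %.4g, p %.3g [J = %d]\n",
              x$method, x$beta, x$ci_low, x$ci_high, x$se, x$pval, x$n_snps))
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, beta = x$beta, se = x$se, ci_low = x$ci_low,
             ci_high = x$ci_high, pval = x$pval, n_snps = x$n_snps,
             stringsAsFactors = FALSE)
}

# normal/t based results
normal_result <- function(method, beta, se, n_snps) {
  q <- qnorm(0.975)
  mr_result(method, beta, se, beta - q * se, beta + q * se,
            norm_p(beta / se), n_snps)
}

t_result <- function(method, beta, se, df, n_snps) {
  q <- qt(0.975, df)
  p <- pmax(2 * pt(-abs(beta / se), df), .Machine$double.xmin)
  mr_result(method, beta, se, beta - q * se, beta + q * se, p, n_snps)
}

#' Wald ratio for a single instrument
#'
#' The per-SNP causal estimate `beta_y / beta_x` with the first-order
#' delta-method standard error `se_y / |beta_x|` (uncertainty in the
#' exposure effect ignored, the usual convention when instruments clear
#' a strength filter). CI and p-value are normal-based.
#'
#' @param beta_x,se_x exposure effect and SE (SE carried for interface
#'   symmetry; it does not enter the first-order SE).
#' @param beta_y,se_y outcome effect and SE.
#' @return An [mr_result()] with method `"wald"`.
#' @examples
#' wald_ratio(-0.0620, 0.0029, -0.0196, 0.0044)  # ratio 0.316
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y) {
  stopifnot(is.finite(beta_x), is.finite(beta_y), se_y > 0)
  if (beta_x == 0) stop("undefined Wald ratio: exposure effect is zero")
  normal_result("wald", beta_y / beta_x, se_y / abs(beta_x), 1L)
}

#' Inverse-variance weighted estimator
#'
#' Combines the per-SNP Wald ratios in a fixed-effect meta-analysis,
#' equivalently an origin-constrained weighted regression of outcome on
#' exposure effects with weights `1/se_y^2`:
#' `theta = sum(bx*by/sy^2) / sum(bx^2/sy^2)`, fixed-effect
#' `se = sum(bx^2/sy^2)^(-1/2)`. Under
#' `model = "multiplicative_re"` the SE is inflated by the residual
#' standard deviation of the constrained fit, floored at 1 (a
#' sensitivity variant; the primary analysis is fixed-effect). P-values
#' come from the standard normal cumulative distribution function.
#'
#' @param instruments an [instrument_set()].
#' @param model `"fixed"` (default) or `"multiplicative_re"`.
#' @return An [mr_result()] with method `"ivw"`.
#' @examples
#' fx <- load_fixture("5-oxoproline")
#' x <- harmonize_pair(fx$exposure, fx$outcome)$instruments
#' mr_ivw(x)  # 0.235 (0.137, 0.333)
#' @export
mr_ivw <- function(instruments, model = c("fixed", "multiplicative_re")) {
  stopifnot(inherits(instruments, "instrument_set"))
  model <- match.arg(model)
  bx <- instruments$beta_x; by <- instruments$beta_y
  sy <- instruments$se_y; J <- instruments$J
  if (all(bx == 0)) stop("degenerate weights: all exposure effects are zero")
  sxx <- sum(bx^2 / sy^2)
  theta <- sum(bx * by / sy^2) / sxx
  se <- sqrt(1 / sxx)
  if (model == "multiplicative_re" && J > 1) {
    disp <- sqrt(sum((by - theta * bx)^2 / sy^2) / (J - 1))
    se <- se * max(1, disp)
  }
  normal_result("ivw", theta, se, J)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with a
#' free intercept and weights `1/se_y^2`, after orienting every SNP to a
#' positive exposure effect (applied internally; the intercept is only
#' identified in that frame). The slope is the causal estimate under the
#' InSIDE assumption; the intercept estimates average directional
#' pleiotropy, and its p-value is the Egger pleiotropy test. Standard
#' errors are inflated by the residual standard deviation floored at 1,
#' with t-based inference on `J - 2` degrees of freedom.
#'
#' @param instruments an [instrument_set()] with at least 3 SNPs.
#' @return List with elements `slope` and `intercept`, both
#'   [mr_result()] (methods `"egger_slope"`, `"egger_intercept"`).
#' @examples
#' fx <- load_fixture("5-oxoproline")
#' x <- harmonize_pair(fx$exposure, fx$outcome)$instruments
#' mr_egger(x)$slope  # 0.361
#' @export
mr_egger <- function(instruments) {
  stopifnot(inherits(instruments, "instrument_set"))
  J <- instruments$J
  if (J < 3L) stop("MR-Egger requires at least 3 instruments")
  x <- orient_positive(instruments)
  bx <- x$beta_x; by <- x$beta_y; w <- 1 / x$se_y^2
  s0 <- sum(w); s1 <- sum(w * bx); s2 <- sum(w * bx^2)
  sy1 <- sum(w * by); sxy <- sum(w * bx * by)
  det <- s0 * s2 - s1^2
  if (det <= 0) stop("exposure effects are collinear; Egger fit undefined")
  slope <- (s0 * sxy - s1 * sy1) / det
  inter <- (s2 * sy1 - s1 * sxy) / det
  rss <- sum(w * (by - inter - slope * bx)^2)
  disp <- max(1, sqrt(rss / (J - 2)))
  se_slope <- sqrt(s0 / det) * disp
  se_inter <- sqrt(s2 / det) * disp
  list(slope = t_result("egger_slope", slope, se_slope, J - 2, J),
       intercept = t_result("egger_intercept", inter, se_inter, J - 2, J))
}

# interpolated weighted median of ratios r with positive weights w
wm_point <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(r[1])
  if (p[length(p)] <= 0.5) return(r[length(r)])
  approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' The 50th percentile of the per-SNP Wald ratios under standardized
#' inverse-variance weights (`bx^2/sy^2`, the inverse of the first-order
#' ratio variance): ratios are sorted, cumulative midpoint weights
#' `p_j = (S_j - w_j/2)/S` formed, and the ratio linearly interpolated
#' at `p = 0.5`. Consistent when at least half the weight comes from
#' valid instruments. The point estimate is deterministic; its standard
#' error comes from a parametric bootstrap (resampling `beta_x`,
#' `beta_y` from normal distributions at their reported SEs), so supply
#' `seed` for reproducibility.
#'
#' @param instruments an [instrument_set()] with at least 3 SNPs and no
#'   zero exposure effect.
#' @param n_boot bootstrap replicates for the SE, default 1000.
#' @param seed integer seed for the bootstrap, or `NULL`.
#' @return An [mr_result()] with method `"weighted_median"`.
#' @examples
#' fx <- load_fixture("5-oxoproline")
#' x <- harmonize_pair(fx$exposure, fx$outcome)$instruments
#' weighted_median(x, seed = 1)  # 0.311
#' @export
weighted_median <- function(instruments, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(instruments, "instrument_set"))
  J <- instruments$J
  if (J < 3L) stop("weighted median requires at least 3 instruments")
  bx <- instruments$beta_x; sx <- instruments$se_x
  by <- instruments$beta_y; sy <- instruments$se_y
  if (any(bx == 0)) stop("undefined Wald ratio: exposure effect is zero")
  est <- wm_point(by / bx, bx^2 / sy^2)
  boot <- with_seed(seed, function() {
    vapply(seq_len(n_boot), function(b) {
      bxs <- rnorm(J, bx, sx)
      bys <- rnorm(J, by, sy)
      wm_point(bys / bxs, bxs^2 / sy^2)
    }, numeric(1))
  })
  normal_result("weighted_median", est, sd(boot), J)
}

# leave-one-out IVW estimates, vectorized over SNPs
ivw_loo <- function(bx, by, sy) {
  w <- 1 / sy^2
  (sum(w * bx * by) - w * bx * by) / (sum(w * bx^2) - w * bx^2)
}

#' MR-PRESSO pleiotropy residual sum of squares and outlier test
#'
#' Simulation-based detection and correction of horizontal pleiotropic
#' outliers. The observed statistic is the weighted residual sum of
#' squares `RSS = sum((by_j - theta_(-j) bx_j)^2 / sy_j^2)` where
#' `theta_(-j)` is the leave-one-out IVW estimate. A null distribution
#' is built from `n_sim` parametric draws `by* ~ N(theta_(-j) bx, sy)`,
#' `bx* ~ N(bx, sx)` with the leave-one-out estimates recomputed per
#' draw; the global p-value is the upper-tail fraction with the usual
#' +1 correction (so the smallest attainable p is `1/(n_sim+1)`).
#' Per-SNP squared residuals are compared against their simulated
#' distributions and flagged as outliers below the Bonferroni bar
#' `outlier_alpha / J`; the corrected estimate is IVW on the survivors.
#' The distortion test compares the raw-vs-corrected shift against the
#' shift obtained when random instrument subsets of the same size as the
#' outlier set are removed.
#'
#' @param instruments an [instrument_set()] with at least 4 SNPs.
#' @param n_sim simulation replicates, default 1000 (10000 gives a
#'   tighter Monte-Carlo error on the global p).
#' @param outlier_alpha family-wise level for outlier flagging,
#'   default 0.05.
#' @param seed integer seed, or `NULL`.
#' @return An object of class `presso_result`: `global_rss`,
#'   `global_pval`, `outlier_indices`, `outlier_pvals`, `raw` and
#'   `corrected` ([mr_result()], methods `"presso_raw"` /
#'   `"presso_corrected"`) and `distortion_pval` (`NA` when no outlier
#'   is flagged).
#' @examples
#' fx <- load_fixture("5-oxoproline")
#' x <- harmonize_pair(fx$exposure, fx$outcome)$instruments
#' mr_presso(x, n_sim = 500, seed = 7)$global_pval
#' @export
mr_presso <- function(instruments, n_sim = 1000, outlier_alpha = 0.05,
                      seed = NULL) {
  stopifnot(inherits(instruments, "instrument_set"), n_sim >= 1)
  J <- instruments$J
  if (J < 4L) stop("MR-PRESSO requires at least 4 instruments")
  bx <- instruments$beta_x; sx <- instruments$se_x
  by <- instruments$beta_y; sy <- instruments$se_y
  w <- 1 / sy^2

  th_loo <- ivw_loo(bx, by, sy)
  obs_res2 <- w * (by - th_loo * bx)^2
  obs_rss <- sum(obs_res2)

  sim <- with_seed(seed, function() {
    BX <- matrix(rnorm(n_sim * J, rep(bx, each = n_sim),
                       rep(sx, each = n_sim)), nrow = n_sim)
    BY <- matrix(rnorm(n_sim * J, rep(th_loo * bx, each = n_sim),
                       rep(sy, each = n_sim)), nrow = n_sim)
    sxy <- (BX * BY) %*% w
    sxx <- (BX * BX) %*% w
    TH <- (c(sxy) - (BX * BY) * rep(w, each = n_sim)) /
          (c(sxx) - (BX * BX) * rep(w, each = n_sim))
    RES2 <- (BY - TH * BX)^2 * rep(w, each = n_sim)
    list(rss = rowSums(RES2), res2 = RES2)
  })

  global_pval <- (sum(sim$rss >= obs_rss) + 1) / (n_sim + 1)
  outlier_pvals <- (colSums(sim$res2 >= rep(obs_res2, each = n_sim)) + 1) /
    (n_sim + 1)
  outliers <- which(outlier_pvals < outlier_alpha / J)

  raw <- mr_ivw(instruments)
  raw$method <- "presso_raw"
  if (length(outliers) == J)
    stop("no instruments survive outlier removal")
  keep <- setdiff(seq_len(J), outliers)
  corrected <- mr_ivw(instrument_subset(instruments, keep))
  corrected$method <- "presso_corrected"

  distortion_pval <- NA_real_
  if (length(outliers) > 0L) {
    d_obs <- raw$beta - corrected$beta
    d_null <- with_seed(if (is.null(seed)) NULL else seed + 1L, function() {
      vapply(seq_len(n_sim), function(b) {
        drop_set <- sample(keep, length(outliers))
        sub <- setdiff(seq_len(J), drop_set)
        raw$beta - sum(w[sub] * bx[sub] * by[sub]) /
          sum(w[sub] * bx[sub]^2)
      }, numeric(1))
    })
    distortion_pval <- (sum(abs(d_null) >= abs(d_obs)) + 1) / (n_sim + 1)
  }

  structure(list(global_rss = obs_rss, global_pval = global_pval,
                 outlier_indices = outliers,
                 outlier_pvals = outlier_pvals,
                 raw = raw, corrected = corrected,
                 distortion_pval = distortion_pval,
                 n_sim = n_sim),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS %.4g, global p %.4g (n_sim %d)\n",
              x$global_rss, x$global_pval, x$n_sim))
  if (length(x$outlier_indices))
    cat("  outliers at index:", paste(x$outlier_indices, collapse = ", "),
        sprintf("| distortion p %.3g\n", x$distortion_pval))
  else cat("  no outliers flagged\n")
  print(x$raw); print(x$corrected)
  invisible(x)
}
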