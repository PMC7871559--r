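#' Simulation scenarios for paired GWAS summary statistics
#'
#' Defines the generative model behind [simulate_pair()]. Each of `J`
#' independent variants j has a true exposure effect `gamma_j` (uniform
#' magnitude over `gamma_range`, random sign by default) and a direct
#' (pleiotropic) outcome effect `alpha_j`; the true outcome effect is
#' `Gamma_j = theta * gamma_j + alpha_j'`, where `alpha_j'` is
#' `alpha_j` expressed relative to the exposure-increasing allele (so
#' directional pleiotropy keeps its direction after instruments are
#' oriented to positive exposure effects). Observed effects are drawn
#' as `beta_x ~ N(gamma, sigma_x)`, `beta_y ~ N(Gamma, sigma_y)` with
#' the standard GWAS standard error
#' `sigma^2 = 1 / (2 maf (1 - maf) n)` for a variance-1 trait.
#'
#' `alpha_j = pleio_mean + pleio_sd * (rho z_j + sqrt(1 - rho^2) e_j)`
#' where `z_j` is the standardized instrument-strength magnitude and
#' `e_j ~ N(0,1)`: `rho = inside_violation` is the correlation between
#' direct effects and instrument strength (0 = InSIDE holds). A
#' fraction `outlier_frac` of variants receive an extra direct effect
#' of `outlier_shift` outcome standard errors with random sign.
#'
#' @param theta true causal effect.
#' @param J instrument count.
#' @param n_x,n_y exposure / outcome GWAS sample sizes. Defaults mirror
#'   the study behind the worked example (7824 metabolomics samples;
#'   269867 in the intelligence meta-analysis).
#' @param gamma_range magnitude range of true exposure effects.
#' @param gamma_sign `"random"` or `"positive"`.
#' @param pleio_mean,pleio_sd directional / balanced pleiotropy
#'   parameters (0, 0 switches pleiotropy off).
#' @param inside_violation correlation in \[-1, 1\] between direct
#'   effects and instrument strength.
#' @param outlier_frac fraction of variants planted as outliers, in
#'   \[0, 1).
#' @param outlier_shift outlier magnitude in units of `sigma_y`.
#' @param maf_range allele-frequency range (kept away from 0 and 0.5 so
#'   the SE formula is well conditioned).
#' @param seed integer seed or `NULL`.
#' @return An object of class `mr_scenario`.
#' @seealso [simulate_pair()], [scenario_presets()]
#' @export
mr_scenario <- function(theta = 0, J = 25, n_x = 7824, n_y = 269867,
                        gamma_range = c(0.05, 0.15),
                        gamma_sign = c("random", "positive"),
                        pleio_mean = 0, pleio_sd = 0,
                        inside_violation = 0, outlier_frac = 0,
                        outlier_shift = 10, maf_range = c(0.1, 0.5),
                        seed = NULL) {
  gamma_sign <- match.arg(gamma_sign)
  if (!is.numeric(J) || J < 1) stop("J must be at least 1")
  if (n_x < 2 || n_y < 2) stop("sample sizes must be at least 2")
  if (outlier_frac < 0 || outlier_frac >= 1)
    stop("outlier_frac must lie in [0, 1)")
  if (abs(inside_violation) > 1)
    stop("inside_violation must lie in [-1, 1]")
  if (pleio_sd < 0) stop("pleio_sd must be non-negative")
  stopifnot(length(gamma_range) == 2L, gamma_range[1] > 0,
            diff(gamma_range) >= 0,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] < 1)
  structure(list(theta = theta, J = as.integer(J), n_x = n_x, n_y = n_y,
                 gamma_range = gamma_range, gamma_sign = gamma_sign,
                 pleio_mean = pleio_mean, pleio_sd = pleio_sd,
                 inside_violation = inside_violation,
                 outlier_frac = outlier_frac,
                 outlier_shift = outlier_shift,
                 maf_range = maf_range, seed = seed),
            class = "mr_scenario")
}

# non-palindromic allele pairs only, so harmonization is deterministic
ALLELE_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                      c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

#' Simulate paired exposure/outcome summary statistics
#'
#' Draws one realization of the scenario's generative model and returns
#' exposure and outcome [summary_table()] objects ready for the full
#' pipeline (consistent non-palindromic alleles, allele frequencies,
#' normal-theory p-values, sample sizes) plus a truth record retaining
#' `gamma`, `alpha`, the outlier labels and `theta`. Output is
#' bit-reproducible for a fixed scenario seed.
#'
#' @param scenario an [mr_scenario()].
#' @return List of class `mr_sim`: `exposure`, `outcome`
#'   ([summary_table()]) and `truth` (data frame with attribute
#'   `"theta"`).
#' @examples
#' sim <- simulate_pair(mr_scenario(theta = 0.3, J = 10, seed = 1))
#' mr_ivw(harmonize_pair(sim$exposure, sim$outcome)$instruments)
#' @export
simulate_pair <- function(scenario) {
  stopifnot(inherits(scenario, "mr_scenario"))
  sc <- scenario
  with_seed(sc$seed, function() {
    J <- sc$J
    maf <- runif(J, sc$maf_range[1], sc$maf_range[2])
    gmag <- runif(J, sc$gamma_range[1], sc$gamma_range[2])
    gsign <- if (sc$gamma_sign == "random")
      sample(c(-1, 1), J, replace = TRUE) else rep(1, J)
    gamma <- gsign * gmag

    sigma_x <- 1 / sqrt(2 * maf * (1 - maf) * sc$n_x)
    sigma_y <- 1 / sqrt(2 * maf * (1 - maf) * sc$n_y)

    alpha <- numeric(J)
    if (sc$pleio_mean != 0 || sc$pleio_sd > 0) {
      rho <- sc$inside_violation
      z <- if (sd(gmag) > 0) (gmag - mean(gmag)) / sd(gmag) else rep(0, J)
      alpha <- sc$pleio_mean +
        sc$pleio_sd * (rho * z + sqrt(1 - rho^2) * rnorm(J))
    }
    is_outlier <- rep(FALSE, J)
    n_out <- round(sc$outlier_frac * J)
    if (n_out > 0) {
      idx <- sample.int(J, n_out)
      is_outlier[idx] <- TRUE
      alpha[idx] <- alpha[idx] +
        sample(c(-1, 1), n_out, replace = TRUE) *
          sc$outlier_shift * sigma_y[idx]
    }
    # direct effects act relative to the exposure-increasing allele
    alpha <- gsign * alpha
    Gamma <- sc$theta * gamma + alpha

    beta_x <- rnorm(J, gamma, sigma_x)
    beta_y <- rnorm(J, Gamma, sigma_y)
    pair <- ALLELE_PAIRS[sample.int(nrow(ALLELE_PAIRS), J, replace = TRUE), ,
                         drop = FALSE]
    ids <- sprintf("snp%04d", seq_len(J))
    mk <- function(beta, se, n, trait)
      summary_table(data.frame(
        snp_id = ids, chrom = NA, effect_allele = pair[, 1],
        other_allele = pair[, 2], eaf = maf, beta = beta, se = se,
        pval = norm_p(beta / se), n = n, stringsAsFactors = FALSE), trait)
    truth <- data.frame(snp_id = ids, maf = maf, gamma = gamma,
                        alpha = alpha, is_outlier = is_outlier,
                        stringsAsFactors = FALSE)
    attr(truth, "theta") <- sc$theta
    structure(list(exposure = mk(beta_x, sigma_x, sc$n_x, "sim_exposure"),
                   outcome = mk(beta_y, sigma_y, sc$n_y, "sim_outcome"),
                   truth = truth),
              class = "mr_sim")
  })
}

#' Named scenario presets
#'
#' Canonical study conditions used throughout the test-suite:
#'
#' * `null`: no causal effect, valid instruments, study-scale GWAS
#'   sizes (type-I error checks).
#' * `causal_clean`: `theta = 0.3`, `J = 25` (echoing the 25-SNP worked
#'   example), no pleiotropy; the exposure GWAS is large (1e5) so
#'   instrument effects are essentially noise-free and estimator bias
#'   reflects the estimators, not weak-instrument attenuation.
#' * `balanced_pleiotropy`: direct effects ~ N(0, 0.01), InSIDE holds.
#' * `directional_pleiotropy`: consistent moderate direct effects
#'   ~ N(0.02, 0.005), InSIDE holds — the Egger intercept should
#'   recover 0.02.
#' * `inside_violated`: balanced direct effects correlated 0.7 with
#'   instrument strength.
#' * `planted_outliers`: `J = 50` with one variant (2%) carrying a
#'   10-sigma direct effect.
#'
#' @param seed optional base seed stored in every preset.
#' @return Named list of [mr_scenario()] objects.
#' @export
scenario_presets <- function(seed = NULL) {
  list(
    null = mr_scenario(theta = 0, J = 25, seed = seed),
    causal_clean = mr_scenario(theta = 0.3, J = 25, n_x = 1e5,
                               seed = seed),
    balanced_pleiotropy = mr_scenario(theta = 0.3, J = 25, n_x = 1e5,
                                      pleio_sd = 0.01, seed = seed),
    directional_pleiotropy = mr_scenario(theta = 0.3, J = 25, n_x = 1e5,
                                         pleio_mean = 0.02,
                                         pleio_sd = 0.005, seed = seed),
    inside_violated = mr_scenario(theta = 0.3, J = 25, n_x = 1e5,
                                  pleio_sd = 0.01,
                                  inside_violation = 0.7, seed = seed),
    planted_outliers = mr_scenario(theta = 0.3, J = 50, n_x = 1e5,
                                   outlier_frac = 0.02, seed = seed))
}

#' Write a simulated pair to disk
#'
#' Writes `exposure.tsv`, `outcome.tsv` (canonical dialect) and
#' `truth.tsv` into `dir`. Byte-identical across runs for a fixed
#' scenario seed.
#'
#' @param sim a [simulate_pair()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "mr_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_summary_stats(sim$exposure, file.path(dir, "exposure.tsv"))
  write_summary_stats(sim$outcome, file.path(dir, "outcome.tsv"))
  tr <- sim$truth
  tr$theta <- attr(sim$truth, "theta")
  num <- vapply(tr, is.numeric, logical(1))
  tr[num] <- lapply(tr[num], fmt_num)
  utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
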