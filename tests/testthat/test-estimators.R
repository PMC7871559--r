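test_that("Wald ratio matches hand arithmetic on the lead SNP", {
  r <- wald_ratio(-0.0620, 0.0029, -0.0196, 0.0044)
  expect_equal(r$beta, -0.0196 / -0.0620, tolerance = 1e-12)
  expect_equal(r$beta, 0.3161, tolerance = 1e-4)
  expect_equal(r$se, 0.0044 / 0.0620, tolerance = 1e-12)
  expect_equal(r$se, 0.0710, tolerance = 1e-3)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.02)$beta, 0)
  id <- wald_ratio(1, 0.01, 0.034, 0.021)
  expect_equal(id$beta, 0.034)
  expect_equal(id$se, 0.021)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.02), "exposure effect is zero")
})

test_that("IVW matches the closed-form weighted average", {
  x <- instrument_set("X", "Y", c("a", "b"), c(1, 1), c(0.1, 0.1),
                      c(0.4, 0.6), c(0.1, 0.1))
  r <- mr_ivw(x)
  expect_equal(r$beta, 0.5, tolerance = 1e-12)
  expect_equal(r$se, sqrt(1 / 200), tolerance = 1e-12)
  expect_equal(r$ci_low, 0.5 - qnorm(0.975) * r$se)
  expect_equal(r$pval, 2 * pnorm(-0.5 / r$se))
})

test_that("IVW with one instrument reduces to the Wald ratio", {
  x <- instrument_set("X", "Y", "a", 0.08, 0.01, 0.02, 0.015)
  ivw <- mr_ivw(x)
  wr <- wald_ratio(0.08, 0.01, 0.02, 0.015)
  expect_equal(ivw$beta, wr$beta)
  expect_equal(ivw$se, wr$se)
  expect_equal(ivw$pval, wr$pval)
})

test_that("IVW is invariant to per-SNP simultaneous sign flips", {
  for (s in 1:5) {
    x <- toy_instruments(J = 10, seed = s)
    flip <- sample(c(-1, 1), 10, replace = TRUE)
    y <- instrument_set("X", "Y", x$snp_ids, flip * x$beta_x, x$se_x,
                        flip * x$beta_y, x$se_y)
    expect_equal(mr_ivw(y)$beta, mr_ivw(x)$beta, tolerance = 1e-12)
    expect_equal(mr_ivw(y)$se, mr_ivw(x)$se, tolerance = 1e-12)
    expect_equal(mr_egger(y)$slope$beta, mr_egger(x)$slope$beta,
                 tolerance = 1e-12)
  }
})

test_that("IVW degenerate inputs error", {
  x <- instrument_set("X", "Y", c("a", "b"), c(0, 0), c(0.1, 0.1),
                      c(0.4, 0.6), c(0.1, 0.1))
  expect_error(mr_ivw(x), "degenerate")
})

test_that("multiplicative random effects never shrink the fixed SE", {
  for (s in 1:5) {
    x <- toy_instruments(J = 12, seed = s)
    expect_gte(mr_ivw(x, "multiplicative_re")$se, mr_ivw(x, "fixed")$se)
    expect_equal(mr_ivw(x, "multiplicative_re")$beta,
                 mr_ivw(x, "fixed")$beta)
  }
})

test_that("Egger recovers an exact affine relationship", {
  bx <- c(0.05, 0.09, 0.14, 0.2)
  x <- instrument_set("X", "Y", paste0("r", 1:4), bx, rep(0.01, 4),
                      0.5 + 0.2 * bx, c(0.01, 0.02, 0.01, 0.03))
  e <- mr_egger(x)
  expect_equal(e$slope$beta, 0.2, tolerance = 1e-10)
  expect_equal(e$intercept$beta, 0.5, tolerance = 1e-10)
})

test_that("Egger agrees with a weighted least-squares oracle", {
  # independent oracle: stats::lm with analytic weights
  for (s in 1:5) {
    x <- orient_positive(toy_instruments(J = 7, seed = s))
    fit <- lm(x$beta_y ~ x$beta_x, weights = 1 / x$se_y^2)
    e <- mr_egger(x)
    expect_equal(e$slope$beta, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(e$intercept$beta, unname(coef(fit)[1]), tolerance = 1e-10)
    # with dispersion estimated > 1 the SEs match lm's as well
    sm <- summary(fit)
    if (sm$sigma > 1)
      expect_equal(e$slope$se, sm$coefficients[2, 2], tolerance = 1e-10)
  }
})

test_that("Egger requires at least three instruments", {
  x <- toy_instruments(J = 2)
  expect_error(mr_egger(x), "at least 3")
})

test_that("weighted median interpolates the 50th weighted percentile", {
  # odd J, equal weights: the middle ratio exactly
  x <- instrument_set("X", "Y", paste0("r", 1:3), c(1, 1, 1),
                      rep(0.01, 3), c(0.2, 0.5, 0.9), rep(0.1, 3))
  expect_equal(weighted_median(x, n_boot = 10, seed = 1)$beta, 0.5)

  # hand interpolation: ratios (0.1, 0.4, 1.0), weights (1, 1, 2)
  # -> midpoints (0.125, 0.375, 0.75), interpolate at 0.5 -> 0.6
  sy <- c(0.1, 0.1, 0.1 / sqrt(2))
  x2 <- instrument_set("X", "Y", paste0("r", 1:3), c(0.1, 0.1, 0.1),
                       rep(0.01, 3), c(0.01, 0.04, 0.10), sy)
  expect_equal(weighted_median(x2, n_boot = 10, seed = 1)$beta, 0.6,
               tolerance = 1e-10)
})

test_that("weighted median lies within the ratio range and is seed-stable", {
  for (s in 1:5) {
    x <- toy_instruments(J = 9, seed = s)
    wm1 <- weighted_median(x, n_boot = 200, seed = 99)
    wm2 <- weighted_median(x, n_boot = 200, seed = 99)
    expect_identical(wm1, wm2)                 # bit-reproducible
    r <- x$beta_y / x$beta_x
    expect_gte(wm1$beta, min(r))
    expect_lte(wm1$beta, max(r))
  }
  expect_error(weighted_median(toy_instruments(J = 2)), "at least 3")
  xz <- instrument_set("X", "Y", c("a", "b", "c"), c(0, 0.1, 0.1),
                       rep(0.01, 3), c(0.1, 0.1, 0.1), rep(0.01, 3))
  expect_error(weighted_median(xz), "exposure effect is zero")
})

test_that("weighted median point estimate matches a brute-force oracle", {
  # oracle: dense grid scan for the weighted-percentile interpolant
  wm_oracle <- function(r, w) {
    o <- order(r); r <- r[o]; w <- w[o] / sum(w)
    p <- cumsum(w) - w / 2
    if (p[1] >= 0.5) return(r[1])
    if (p[length(p)] <= 0.5) return(r[length(r)])
    i <- max(which(p < 0.5))
    r[i] + (r[i + 1] - r[i]) * (0.5 - p[i]) / (p[i + 1] - p[i])
  }
  for (s in 1:20) {
    set.seed(s)
    J <- sample(3:15, 1)
    r <- rnorm(J); w <- runif(J, 0.1, 2)
    bx <- runif(J, 0.5, 1.5)
    sy <- bx / sqrt(w)          # so that bx^2/sy^2 = w
    x <- instrument_set("X", "Y", paste0("r", 1:J), bx, rep(0.01, J),
                        r * bx, sy)
    expect_equal(weighted_median(x, n_boot = 2, seed = 1)$beta,
                 wm_oracle(r, w), tolerance = 1e-10)
  }
})

test_that("MR-PRESSO is null on noiseless consistent data", {
  bx <- seq(0.05, 0.2, length.out = 8)
  x <- instrument_set("X", "Y", paste0("r", 1:8), bx, rep(0.005, 8),
                      0.3 * bx, rep(0.004, 8))
  p <- mr_presso(x, n_sim = 200, seed = 3)
  expect_equal(length(p$outlier_indices), 0L)
  expect_gte(p$global_pval, 0.99)
  expect_true(is.na(p$distortion_pval))
  expect_equal(p$raw$beta, p$corrected$beta)
})

test_that("MR-PRESSO flags a planted 10-sigma outlier", {
  sim <- simulate_pair(mr_scenario(theta = 0.3, J = 50, n_x = 1e5,
                                   outlier_frac = 0.02, seed = 21))
  x <- harmonize_pair(sim$exposure, sim$outcome)$instruments
  # at J = 50 the Bonferroni bar is 0.001, so n_sim must exceed 1000
  # for any SNP to be flaggable at all
  p <- mr_presso(x, n_sim = 2000, seed = 4)
  planted <- which(sim$truth$is_outlier)
  expect_true(planted %in% p$outlier_indices)
  expect_equal(p$corrected$n_snps, 50L - length(p$outlier_indices))
  expect_false(is.na(p$distortion_pval))
  # removing the planted outlier moves the estimate toward the truth
  expect_lte(abs(p$corrected$beta - 0.3), abs(p$raw$beta - 0.3))
})

test_that("MR-PRESSO preconditions and reproducibility", {
  expect_error(mr_presso(toy_instruments(J = 3)), "at least 4")
  x <- toy_instruments(J = 10, seed = 2)
  p1 <- mr_presso(x, n_sim = 100, seed = 11)
  p2 <- mr_presso(x, n_sim = 100, seed = 11)
  expect_identical(p1, p2)
  expect_true(all(p1$outlier_pvals >= 1 / 101))
})
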