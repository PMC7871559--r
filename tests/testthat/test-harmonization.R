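test_that("swapped outcome alleles flip the outcome beta", {
  ex <- stab("rs1", 0.10, 0.01, effect_allele = "A", other_allele = "G")
  ou <- stab("rs1", -0.05, 0.01, effect_allele = "G", other_allele = "A",
             trait = "out")
  h <- harmonize_pair(ex, ou)
  expect_equal(h$instruments$beta_y, 0.05)
  expect_equal(nrow(h$exclusions), 0L)
})

test_that("strand-flip complements are resolved before comparison", {
  ex <- stab("rs1", 0.10, 0.01, effect_allele = "A", other_allele = "G")
  # same physical allele reported on the opposite strand: T/C == A/G
  ou_same <- stab("rs1", 0.07, 0.01, effect_allele = "T",
                  other_allele = "C", trait = "out")
  expect_equal(harmonize_pair(ex, ou_same)$instruments$beta_y, 0.07)
  # opposite-strand and swapped: C/T == G/A -> flip
  ou_swap <- stab("rs1", 0.07, 0.01, effect_allele = "C",
                  other_allele = "T", trait = "out")
  expect_equal(harmonize_pair(ex, ou_swap)$instruments$beta_y, -0.07)
})

test_that("palindromic SNPs follow the policy", {
  ex <- stab("rs1", 0.10, 0.01, effect_allele = "A", other_allele = "T",
             eaf = 0.2)
  ou <- stab("rs1", 0.05, 0.01, effect_allele = "A", other_allele = "T",
             eaf = 0.22, trait = "out")
  expect_error(harmonize_pair(ex, ou, "drop"), "no shared instruments")
  # with a second resolvable SNP the palindrome is logged, not fatal
  ex2 <- stab(c("rs1", "rs2"), c(0.10, 0.08), 0.01,
              effect_allele = c("A", "A"), other_allele = c("T", "G"),
              eaf = 0.2)
  ou2 <- stab(c("rs1", "rs2"), c(0.05, 0.03), 0.01,
              effect_allele = c("A", "A"), other_allele = c("T", "G"),
              eaf = 0.22, trait = "out")
  h <- harmonize_pair(ex2, ou2, "drop")
  expect_equal(h$exclusions$reason, "palindromic")
  expect_equal(h$instruments$snp_ids, "rs2")

  # keep_if_eaf: frequencies on the same side of 0.5 keep the sign
  h2 <- harmonize_pair(ex2, ou2, "keep_if_eaf")
  expect_equal(h2$instruments$beta_y, c(0.05, 0.03))
  # opposite sides imply a strand flip of the effect allele
  ou3 <- stab("rs1", 0.05, 0.01, effect_allele = "A", other_allele = "T",
              eaf = 0.8, trait = "out")
  h3 <- harmonize_pair(ex, ou3, "keep_if_eaf")
  expect_equal(h3$instruments$beta_y, -0.05)
  # ambiguous (eaf near 0.5) or missing eaf: dropped even under keep_if_eaf
  ou4 <- stab("rs1", 0.05, 0.01, effect_allele = "A", other_allele = "T",
              eaf = 0.52, trait = "out")
  expect_error(harmonize_pair(ex, ou4, "keep_if_eaf"),
               "no shared instruments")
})

test_that("irreconcilable alleles are excluded with a reason", {
  ex <- stab(c("rs1", "rs2"), c(0.1, 0.1), 0.01,
             effect_allele = c("A", "A"), other_allele = c("G", "G"))
  ou <- stab(c("rs1", "rs2"), c(0.05, 0.05), 0.01,
             effect_allele = c("A", "A"), other_allele = c("C", "G"),
             trait = "out")
  h <- harmonize_pair(ex, ou)
  expect_equal(h$exclusions,
               data.frame(snp_id = "rs1", reason = "allele_mismatch",
                          stringsAsFactors = FALSE))
  # exclusions + retained = shared
  expect_equal(nrow(h$exclusions) + h$instruments$J, 2L)
})

test_that("empty intersection raises 'no shared instruments'", {
  ex <- stab("rs1", 0.1, 0.01)
  ou <- stab("rs2", 0.1, 0.01, trait = "out")
  expect_error(harmonize_pair(ex, ou), "no shared instruments")
})

test_that("harmonization is idempotent", {
  sim <- simulate_pair(mr_scenario(theta = 0.3, J = 15, seed = 5))
  h1 <- harmonize_pair(sim$exposure, sim$outcome)
  # rebuild an outcome table already expressed on the exposure alleles
  ou2 <- summary_table(data.frame(
    snp_id = h1$instruments$snp_ids,
    effect_allele = sim$exposure$effect_allele,
    other_allele = sim$exposure$other_allele,
    beta = h1$instruments$beta_y, se = h1$instruments$se_y,
    pval = sim$outcome$pval, eaf = sim$outcome$eaf,
    stringsAsFactors = FALSE), "out")
  h2 <- harmonize_pair(sim$exposure, ou2)
  expect_equal(h2$instruments$beta_y, h1$instruments$beta_y)
  expect_equal(h2$instruments$beta_x, h1$instruments$beta_x)
  expect_equal(nrow(h2$exclusions), 0L)
})

test_that("pre-harmonized tables are paired by snp_id without allele logic", {
  fx <- load_fixture("5-oxoproline")
  h <- harmonize_pair(fx$exposure, fx$outcome)
  expect_equal(h$instruments$J, 25L)  # includes 3 A/T palindromes
  expect_equal(nrow(h$exclusions), 0L)
})

test_that("orient_positive flips pairs and preserves Wald ratios", {
  x <- instrument_set("X", "Y", c("rs11986602", "b"),
                      beta_x = c(-0.0620, 0.01), se_x = c(0.0029, 0.002),
                      beta_y = c(-0.0196, 0.001), se_y = c(0.0044, 0.003))
  o <- orient_positive(x)
  expect_equal(o$beta_x[1], 0.0620)
  expect_equal(o$beta_y[1], 0.0196)
  expect_equal(o$beta_y / o$beta_x, x$beta_y / x$beta_x)
  # all-positive input unchanged
  expect_identical(orient_positive(o), o)
  # property over random sets
  for (s in 1:10) {
    xi <- toy_instruments(J = 8, seed = s)
    oi <- orient_positive(xi)
    expect_true(all(oi$beta_x >= 0))
    expect_equal(oi$beta_y / oi$beta_x, xi$beta_y / xi$beta_x)
  }
})

test_that("instrument_set validates its invariants", {
  expect_error(instrument_set("X", "Y", c("a", "a"), c(1, 1), c(1, 1),
                              c(1, 1), c(1, 1)), "duplicate")
  expect_error(instrument_set("X", "Y", "a", 1, 0, 1, 1), "positive")
  expect_error(instrument_set("X", "Y", c("a", "b"), 1, c(1, 1),
                              c(1, 1), c(1, 1)), "length")
  expect_error(instrument_set("X", "Y", character(), numeric(),
                              numeric(), numeric(), numeric()),
               "at least one")
})
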