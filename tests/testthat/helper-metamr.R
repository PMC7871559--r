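# quick summary_table builder with sensible defaults
stab <- function(snp_id, beta, se, pval = rep(1e-8, length(snp_id)),
                 effect_allele = rep("A", length(snp_id)),
                 other_allele = rep("G", length(snp_id)),
                 eaf = NA, n = NA, trait = "trait",
                 pre_harmonized = FALSE) {
  summary_table(data.frame(snp_id = snp_id, effect_allele = effect_allele,
                           other_allele = other_allele, beta = beta,
                           se = se, pval = pval, eaf = eaf, n = n,
                           stringsAsFactors = FALSE),
                trait_id = trait, pre_harmonized = pre_harmonized)
}

# small instrument set used across estimator tests
toy_instruments <- function(J = 5, seed = 42) {
  set.seed(seed)
  instrument_set("X", "Y", paste0("rs", seq_len(J)),
                 beta_x = runif(J, 0.05, 0.15) * sample(c(-1, 1), J, TRUE),
                 se_x = runif(J, 0.005, 0.02),
                 beta_y = rnorm(J, 0.03, 0.02),
                 se_y = runif(J, 0.005, 0.02))
}

# harmonized instruments of the 25-SNP worked example
oxo_instruments <- function() {
  fx <- load_fixture("5-oxoproline")
  harmonize_pair(fx$exposure, fx$outcome)$instruments
}
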