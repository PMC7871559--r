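# Bundled data files

* `oxoproline_exposure.tsv` / `oxoproline_outcome.tsv` — transcription of
  the published 25-SNP instrument table for 5-oxoproline (exposure side:
  metabolomics GWAS of 7824 adults; outcome side: intelligence GWAS
  meta-analysis). Effect-allele frequencies and per-SNP sample sizes are
  not printed in the source table and are carried as NA. The two tables
  are pre-harmonized: effects are already expressed on a common effect
  allele (A1).
* `synthetic_*_{exposure,outcome}.tsv` — SYNTHETIC stand-ins generated by
  metamr's own simulator (`simulate_pair()`), with causal effects chosen
  near the published point estimates for the corresponding metabolites.
  They are not the published supplementary instrument tables and must not
  be used to reproduce printed per-SNP numbers.

All files use the canonical whitespace/tab dialect:
`SNP A1 A2 freq b se p N` (plus optional `gene`, `chrom`).
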