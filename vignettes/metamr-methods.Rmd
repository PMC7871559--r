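---
title: "Methods: two-sample MR for metabolome-wide screens"
author: "metamr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR for metabolome-wide screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamr)
```

## The estimation problem

Two-sample Mendelian randomization estimates the causal effect of an
exposure on an outcome from two independent GWAS: per-SNP exposure
effects $\hat\beta_{Xj} \pm \sigma_{Xj}$ and outcome effects
$\hat\beta_{Yj} \pm \sigma_{Yj}$, $j = 1,\dots,J$. A variant is a
valid instrument if it is (i) associated with the exposure, (ii)
independent of confounders, and (iii) affects the outcome only through
the exposure. Under validity each Wald ratio
$\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the same causal effect
$\theta$; the estimators differ in how they combine the ratios and in
which violations of (iii) they tolerate.

`metamr` targets metabolome-wide screens: hundreds of genetically
determined metabolite levels tested against one outcome, with
instrument selection, harmonization, four estimators, heterogeneity
diagnostics, significance tiering, replication and pathway
over-representation behind one fitting interface (`mr_fit()`) and one
screening driver (`screen_exposures()`).

## Instrument selection

Candidates pass three sequential filters, all tunable via
`mr_config()`:

* **Association**: `p_threshold = 1e-5` (strict `<`). Metabolite GWAS
  of a few thousand samples rarely yield multiple genome-wide
  significant loci; the suggestive cut trades instrument strength for
  explained variance and is the convention for metabotype screens.
* **Independence**: greedy LD clumping (`clump_greedy()`), visiting
  SNPs by ascending p-value (ties broken lexicographically by rsID for
  determinism) and discarding any SNP within `clump_kb = 500` kb of a
  kept SNP with $r^2 \ge$ `clump_r2 = 0.1`. LD comes from a
  user-supplied pairwise table (`ld_table()`); absent pairs count as
  $r^2 = 0$ and SNPs without coordinates are treated as their own
  chromosome, so the procedure degrades explicitly rather than
  guessing. Computing LD from genotype panels is out of scope.
* **Strength**: per-SNP $R^2_j = z_j^2/(z_j^2 + n - 2)$ with
  $z_j = \hat\beta_{Xj}/\sigma_{Xj}$, and
  $F_j = (n-2)R^2_j/(1-R^2_j)$, which algebraically equals $z_j^2$.
  This is the standard summary-level approximation — it needs only the
  printed columns plus a sample size, not allele frequencies. SNPs are
  kept when $F_j$ is strictly greater than `f_min = 10`. When per-SNP
  sample sizes are absent and no `n_exposure` override is given, the
  filter is skipped and the skip recorded in the screen row rather
  than silently inventing an $n$.

## Harmonization

`harmonize_pair()` re-expresses every shared SNP on the exposure's
effect allele: swapped allele pairs flip the outcome beta, opposite
strand reports are resolved by complementing before comparison, and
irreconcilable pairs are excluded with reason codes. Palindromic SNPs
(A/T, C/G) are ambiguous from alleles alone; the default policy drops
them. The alternative `keep_if_eaf` infers orientation from allele
frequencies, requiring both frequencies to be present, further than
`eaf_tolerance = 0.08` from 0.5, and to agree on the minor-allele
scale within the same tolerance. The source study does not state its
palindrome handling, so the default is chosen conservatively and is
not claimed to be the study's rule. The bundled instrument tables are
printed already aligned — they carry a documented `pre_harmonized`
flag and are paired by rsID, which also protects their three A/T
palindromes from being dropped.

## Estimators

**IVW (primary).** Fixed-effect combination of the Wald ratios,
equivalently origin-constrained WLS of $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$ with weights $\sigma_{Yj}^{-2}$. P-values use the
standard normal CDF. A multiplicative random-effects variant (SE
inflated by the residual SD, floored at 1) is available by flag for
sensitivity; the primary model stays fixed-effect.

**MR-Egger.** Same regression with a free intercept, after orienting
all SNPs to $\hat\beta_{Xj} \ge 0$ (applied internally; the intercept
is only identified in that frame). Inference is t-based on $J-2$ df
with the dispersion floored at 1 — the dominant convention where the
source is silent. The intercept is the directional-pleiotropy test.

**Weighted median.** Ratios sorted, cumulative midpoint weights
$p_j = (S_j - w_j/2)/S$ formed from the inverse first-order ratio
variances $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$, and the ratio
linearly interpolated at $p = 0.5$ (clamped to the extreme ratios when
0.5 falls outside the midpoint range). The point estimate is
deterministic; the SE is a parametric bootstrap (default
`n_boot = 1000`) resampling both effect vectors at their reported SEs,
so a seed is required for reproducible intervals.

**MR-PRESSO.** Observed statistic: leave-one-out weighted RSS
$\sum_j \sigma_{Yj}^{-2}(\hat\beta_{Yj} - \hat\theta_{(-j)}\hat\beta_{Xj})^2$.
Null distribution: `n_sim` parametric draws of both effect vectors
with leave-one-out estimates recomputed per draw; empirical p-values
carry the +1 correction, so the attainable floor is
$1/(n_\mathrm{sim}+1)$. Per-SNP outliers are flagged below the
Bonferroni bar $\alpha/J$ — note that at $J = 50$ this bar is 0.001,
so `n_sim` must exceed 1000 for any flag to be attainable; the default
is 1000 and diagnostic runs should use 2000–10000. The corrected
estimate is IVW on the survivors; the distortion test compares the
raw-vs-corrected shift against shifts from removing random subsets of
the same size.

**Numerical choices.** Exact normal/t quantiles are used rather than
the rounded 1.96 (difference below 0.01% of the interval width, well
under reported precision). P-values are floored at the smallest
positive double so they remain in $(0, 1]$. Zero exposure effects make
ratios undefined and raise errors rather than infinities. All
estimator cores are closed-form sums; the Egger normal equations are
solved explicitly and cross-checked against `stats::lm` in the tests.

## Tiering, robustness and replication

With $m$ exposures screened, `tier` is `bonferroni_significant` when
the IVW p is below $\alpha/m$ (1.03e-4 at $m = 486$), `suggestive`
below $\alpha$, else `null`; $m$ defaults to the number of exposures
supplied and can be overridden to apply a panel-wide bar to a subset.
The robustness gate calls an association robust when all three
sensitivity estimators reach $p < 0.05$ *and* agree in sign with IVW.
Heterogeneity and pleiotropy flags (I² strictly above 25%, Q p, Egger
intercept p, PRESSO global p below 0.05) annotate rows but do not
veto: moderate heterogeneity is common for metabolite instruments and
the gate's job is sensitivity-consistency, not flag-free purity. This
operationalization is the package's definition, chosen to match how
such screens are reported; it is not quoted from any single study.

Replication (`mr_replicate()`) reuses the discovery instruments
against each alternative outcome rather than reselecting per outcome —
reselection would change the estimand between discovery and
replication. Rows with under 50% instrument overlap carry a warning
marker.

## Pathway over-representation

`ora_test()` is an exact one-sided hypergeometric test: for a pathway
of size $K$ in background $N$ with $k$ of $n$ mapped candidates,
$p = P(X \ge k)$ by direct summation of the pmf in log space. The
background defaults to the library universe (union of all sets) unless
an explicit background is supplied — the assayed panel is often the
better universe, and the choice materially changes p-values, so it is
exposed rather than hidden. Raw p-values are reported at a 0.05
significance column with no cross-pathway correction, matching common
practice for small metabolite sets. Published pathway p-values from
web tools are generally not reproducible without their exact library
versions and background; the bundled toy examples are illustrative.

## The synthetic-data generator

`simulate_pair()` draws, for each of $J$ independent variants, a MAF
$\sim U(0.1, 0.5)$, a true exposure effect $\gamma_j$ with magnitude
$U(0.05, 0.15)$ and random sign, and a direct effect $\alpha_j$; the
true outcome effect is $\Gamma_j = \theta\gamma_j + \alpha_j'$ with
observed effects $\hat\beta \sim N(\cdot, \sigma)$,
$\sigma^2 = 1/(2\,\mathrm{maf}(1-\mathrm{maf})\,n)$ (variance-1
traits). Two modelling points deserve emphasis:

* **Direct effects are anchored to the exposure-increasing allele**
  ($\alpha_j' = \mathrm{sign}(\gamma_j)\,\alpha_j$). Allele coding is
  arbitrary, so "directional" pleiotropy is only meaningful relative
  to an orientation; anchoring to the exposure-increasing allele makes
  the Egger intercept estimand equal `pleio_mean` after the
  positive-$\beta_X$ orientation. Without this, random allele coding
  averages any directional effect to zero.
* **InSIDE violation** is a latent-correlation construction:
  $\alpha_j = \mu + \tau(\rho z_j + \sqrt{1-\rho^2}\,e_j)$ with $z_j$
  the standardized instrument-strength magnitude, giving
  $\mathrm{cor}(\alpha, |\gamma|) = \rho$ exactly in expectation.

Presets (`scenario_presets()`) fix the study conditions used by the
test-suite: `null` keeps the study-scale sample sizes (7824 exposure /
269867 outcome — size of a test is insensitive to instrument noise
when $\theta = 0$); the recovery presets (`causal_clean`,
`*_pleiotropy`, `inside_violated`, `planted_outliers`) use a large
exposure GWAS ($n_x = 10^5$, $10^6$ for the coverage check) so that
instrument effects are essentially noise-free. This is deliberate: at
$n_x = 7824$ against a 270k-sample outcome GWAS, weak-instrument
regression dilution biases IVW by roughly two combined standard errors
at $\theta = 0.3$ — a real phenomenon of such designs, but it would
make "does the estimator recover $\theta$" conflate estimator
correctness with instrument-noise attenuation. The directional
pleiotropy preset uses mean 0.02 with SD 0.005 (consistent moderate
direct effects): at SD 0.01 the inflated Egger dispersion roughly
halves the intercept test's power, which would test the scenario's
noise level rather than the estimator.

What the generator does *not* emulate: LD between instruments
(clumping is exercised on hand-built LD tables instead), allele
frequency differences between the two GWAS populations, effect-size /
frequency coupling, sample overlap between exposure and outcome GWAS,
population stratification and dynastic effects. Passing the
simulation suite therefore demonstrates correctness of the estimators
under their own assumptions, not robustness to those additional
real-data complications.

## Problem sizes in the test-suite

The deterministic worked example (25 SNPs) runs in milliseconds.
Simulation-based checks use 2000 replicates for the IVW type-I error,
500 for bias and coverage, 200 for the Egger intercept
identity/power, 20 seeds for MR-PRESSO outlier recovery
(`n_sim = 2000`), 10000 PRESSO draws on the worked example, and a
100-exposure screen (20 causal / 80 null, Bonferroni over 100) for
end-to-end sensitivity and false-positive rate. These sizes put
Monte-Carlo error comfortably inside the asserted bands while keeping
the whole suite around half a minute on one core.

## Known limitations

* Wald-ratio SEs are first order; second-order terms are omitted.
* No proxy-SNP lookup for instruments missing from an outcome GWAS,
  no multi-allelic resolution, no liftover, no GWAS-VCF parsing.
* No mode-based, robust-adjusted-profile-score or multivariable
  estimators, and no bi-directional analysis.
* The clumping implementation is quadratic in candidates per region —
  fine for metabolite instrument counts (tens), not tuned for
  genome-wide clumping of millions of SNPs.
* The bundled instrument tables for dihomo-linoleate and
  p-acetamidophenylglucuronide are synthetic stand-ins generated by
  this package (clearly labelled); only the 5-oxoproline table is a
  transcription of published per-SNP statistics.
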