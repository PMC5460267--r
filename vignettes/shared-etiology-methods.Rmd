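---
title: "Methods: polygenic scans for shared genetic etiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic scans for shared genetic etiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`prscan` tests whether a binary disease trait shares genetic etiology with
quantitative "base" traits, using only GWAS summary statistics on the base
side and individual-level genotypes plus a case/control phenotype on the
target side. This vignette describes the statistical machinery, the choices
behind its defaults, and what the simulation-based tests do and do not show.

## The analysis chain

1. **Candidate genes.** SNPs associated with a trait at `p < 1e-4` (the
   conventional "suggestive" threshold) nominate genes: a gene qualifies
   when the SNP lies in the gene body — exon, intron or UTR all count,
   since they partition the body — or within 100 kb of it. The window is
   motivated by the empirical range of cis-eQTL around genes, applied
   symmetrically around the SNP (strand is ignored), with an inclusive
   boundary: a SNP exactly 100,000 bp away qualifies. The two clauses
   collapse to one interval test on `[start - window, end + window]`.
   Selection runs per study before merging, so the provenance records which
   GWAS contributed each supporting SNP.

2. **Network enrichment.** Candidate sets are scored against
   user-supplied interaction networks with the right-tailed Fisher's exact
   test on the overlap within a declared gene universe; the enrichment
   score is `-log10(p)`. The universe is a *required* input: commercial
   pathway tools score against their proprietary knowledge bases, so no
   default universe could be meaningful. Base 10 is the convention for
   such scores (p-values are reported in decimal scientific notation); a
   natural-log switch exists (`log_base`). Network construction itself is
   out of scope — networks are inputs.

3. **Polygenic risk scores.** Clumping-and-thresholding: after allele
   harmonization (dropping palindromic A/T and C/G SNPs, flipping betas
   where the effect allele matches the target's reference allele), SNPs
   are greedily clumped — the most significant unclumped SNP indexes a
   clump and removes everything within 250 kb at `r² >= 0.1` — and scored
   at seven base p-value thresholds, `p_T ∈ {0.001, 0.05, 0.1, 0.2, 0.3,
   0.4, 0.5}`. The per-sample score at a threshold is the *mean* of
   `beta × dosage` over the selected SNPs (missing dosages mean-imputed per
   SNP at scoring time). These operational choices (window, r², mean
   scoring, palindromic removal) follow the documented defaults of the
   standard scoring tool for this design and are all overridable.

4. **Association.** The phenotype is regressed on the z-standardized
   score by logistic regression; the shared-etiology p-value is the Wald
   test of the score term and the model fit is Nagelkerke's pseudo-R²
   against the covariate-only null,
   `R² = (1 - (L0/L1)^{2/n}) / (1 - L0^{2/n})`. Under (quasi-)separation
   the Wald statistic degenerates, so the result is flagged and the
   p-value falls back to the likelihood-ratio test. Covariates are
   accepted but default to none. "Most predictive threshold" means the
   smallest association p, which coincides with the largest R² in this
   model; both are reported.

5. **Combined base traits.** Matched SNPs of two traits (HDL- and
   LDL-like in the motivating use case) are split by the signs of their
   harmonized betas into four groups — increasing both, decreasing both,
   and the two discordant patterns. SNPs with an exactly zero beta carry
   no sign and are excluded (and counted). Each combined SNP receives the
   equivalent weighted p-value
   `2 / p_eq = 1 / p_HDL + 1 / p_LDL`,
   i.e. the harmonic mean with equal weights, exactly as displayed; it is
   symmetric, bounded by the two inputs, and equals them at equality. The
   combined effect size used for scoring defaults to the arithmetic mean
   of the two betas (sign-consistent within a group by construction);
   `beta_rule` can keep either single trait's beta instead. Clumping of
   combined sets ranks by `p_eq`, because that is the p-value the scoring
   stage consumes.

6. **FDR.** The per-threshold association p-values are aggregated
   (pooled across base sets by default, mirroring how significance stars
   are displayed across traits simultaneously; per-trait families are a
   flag) and corrected by the q-value procedure with the *bootstrap*
   selection of the tuning parameter lambda: `pi0(λ) = #{p > λ} / (m(1-λ))`
   on a grid `λ ∈ {0, 0.05, …, 0.95}`, with 100 bootstrap resamples
   estimating the MSE of each `pi0(λ)` around the grid minimum; the λ
   minimizing it is selected. Corrected values are floored at the
   uncorrected p-values (`q_i >= p_i` always) — relevant precisely when
   `pi0 < 1` and the raw p-values are already small. With families as
   small as the real use case (7 thresholds per trait), pi0 estimation is
   unstable, so below 30 tests the conservative `pi0 = 1` is used unless
   estimation is forced; a Benjamini–Yekutieli option covers the
   dependency-robust reading of FDR under arbitrary dependence. Stars
   annotate `q < 0.05` (`*`) and `q < 0.01` (`**`).

## The synthetic study generator

Real inputs at the scale of the motivating design (a base GWAS of 188,577
individuals; a target of 5,333 cases and 12,019 controls) are neither
shipped nor required. `sim_config()` describes a desk-scale study whose
*structure* matches that design:

- **Genotypes**: haplotypes from a block-structured latent Gaussian
  copula — exchangeable correlation `within_block_r` inside a block,
  independence across blocks — thresholded at the allele-frequency
  quantile; dosage = sum of two haplotypes. Defaults: 10,000 SNPs in 100
  blocks, 5 kb spacing, MAF uniform on (0.05, 0.5). Dichotomization
  attenuates the latent correlation: at `within_block_r = 0.9` the mean
  within-block dosage r² is about 0.32 (population value), not 0.9 — the
  tests assert the attenuated values this copula actually implies.
- **Base summary statistics**: true standardized effects at `n_causal`
  SNPs (Gaussian by default; an equal-magnitude "fixed" spike via
  `effect_dist`), rescaled so the causal SNPs explain `h2_base` per
  trait; the LDL-like effect is sign-concordant with the HDL-like one
  with probability `sign_mix`. Observed betas add sampling noise with
  `se = 1/sqrt(n_base · 2f(1-f))` and two-sided Wald p-values — summary
  statistics are simulated from asymptotic sampling theory rather than by
  simulating 188,577 individuals, which is what makes the base/target
  asymmetry affordable. Default `n_base = 188577`, `h2_base = 0.3`.
- **Target phenotype**: liability threshold. The liability is a weighted
  sum of standardized dosages plus Gaussian noise scaled so the genetic
  share is `h2_liability`; the top `case_fraction` quantile becomes cases
  (case counts are exact; default 0.31 ≈ 5,333/17,352). Target causal
  SNPs are `shared_fraction · n_causal` SNPs reused from the base-causal
  set, with effects proportional to the true base effects — that
  proportionality is what makes the etiology genuinely shared — plus
  independent causal SNPs. Base-causal SNPs are confined to half of the
  LD blocks and target-specific causal SNPs to the other half, so
  `shared_fraction` controls the overlap exactly instead of leaking
  through within-block LD; `target_shared_group` can restrict the shared
  SNPs to one beta-sign group for combined-trait experiments.

What the generator does **not** emulate: realistic human LD maps (blocks
are exchangeable, not decaying), population structure and relatedness,
genotyping error and imputation uncertainty, and ascertainment beyond the
liability quantile. Passing calibration tests therefore demonstrates the
statistical machinery is correct and calibrated *under this model*, not
that any particular real-data result would replicate.

## Numerical and design notes

- p-values are floored at the smallest positive double when Wald
  statistics underflow; the equivalent p-value is computed in reciprocal
  form, which stays positive where the product form would underflow.
- Clumping ties on p are broken by position then SNP id, making runs
  bit-reproducible; every stochastic routine takes an explicit seed, and
  pipeline stages derive independent sub-seeds from the master seed.
- Monomorphic SNPs get `r² = 0` by convention (their correlation is
  undefined) and a zero-variance score yields `p = 1, R² = 0` rather than
  an error.
- BED input is converted to 1-based inclusive coordinates exactly once at
  the boundary; all internal coordinates are 1-based inclusive, which is
  the natural frame for an inclusive "within 100 kb" rule.
- Combined-base standard errors are `sqrt(se₁² + se₂²)/2` (se of the mean
  beta under independence); nothing downstream consumes them, they only
  keep the combined set a valid summary-statistics object.

## Problem sizes used by the test suite

Calibration tests run the full pipeline on simulated studies of 3,000
SNPs × 2,000 samples (2,000 × 1,500 for the combined-trait experiment)
with around 100 replicates per condition, a scale chosen so the whole
suite runs in minutes on one CPU while keeping binomial Monte-Carlo
margins tight enough to be meaningful; margins are always computed for
the replicate count actually used. The threshold-recovery experiment uses
the spike architecture (`effect_dist = "fixed"`, `n_base = 3600`,
`n_causal = 50`, `h2 = 0.5`): that places every causal Wald statistic
near 6 standard deviations — cleanly below `p < 0.001` — while keeping
null-SNP noise large enough that higher thresholds measurably dilute the
score, which is the regime where the most-predictive-threshold question
has a determinate answer. With Gaussian effects some causal SNPs always
straddle any p-value cut, so confinement cannot be constructed there.

## Known limitations

- Summary-level target cohorts are out of scope: association needs
  per-sample scores.
- No imputation, liftover, or multi-allelic handling beyond the first ALT
  allele (with a warning).
- pi0 estimation at `m = 7` is intentionally disabled by default; users
  who force it should treat the resulting q-values with caution.
- The enrichment stage reproduces a published score *formula*; scores are
  only comparable across runs that declare the same universe.
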