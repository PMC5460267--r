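# prscan

Polygenic risk score (PRS) scans for **shared genetic etiology** between
quantitative base traits and a binary disease, with candidate-gene network
enrichment, combined two-trait base sets, and q-value FDR control.

## The problem

Epidemiology can link blood lipid and lipoprotein levels to a
neurodegenerative disease, but association of the *phenotypes* says nothing
about whether the *genetics* overlap. The clumping-and-thresholding PRS
design answers that directly: take SNP weights from a large GWAS of the
quantitative trait (the **base** sample), score every individual of a
case/control cohort (the **target** sample), and test whether the score
predicts disease status. Scanning a ladder of base p-value thresholds
p_T ∈ {0.001, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5} shows where in the
association spectrum the shared signal lives.

`prscan` implements that analysis chain for R:

- **Candidate genes** — SNPs at p < 1e-4 nominate genes within the gene
  body or ±100 kb (inclusive boundary), merged across studies with
  per-study provenance.
- **Network enrichment** — right-tailed Fisher's exact test of the overlap
  between candidates and a network's nodes in an explicit gene universe;
  score = −log10(p).
- **PRS engine** — allele harmonization (palindromic SNPs dropped), greedy
  LD clumping (250 kb, r² ≥ 0.1), mean(β × dosage) scores per threshold,
  logistic association with Nagelkerke R².
- **Combined base traits** — matched SNPs of two traits split by beta sign
  into four groups (e.g. *increased HDL + increased LDL*), each SNP given
  the equivalent weighted p-value **2/p_eq = 1/p_HDL + 1/p_LDL** (the
  harmonic mean) before scoring.
- **FDR** — q-values with bootstrap selection of the lambda tuning
  parameter for the null-proportion estimate, floored so correction never
  drops below the uncorrected p-value; stars at q < 0.05 (\*) and
  q < 0.01 (\*\*).
- **Synthetic studies** — a liability-threshold simulator with block-LD
  genotypes, two correlated base traits observed through summary-statistic
  sampling noise, and a tunable shared-causal fraction, so the whole
  pipeline is testable without any external data.

## Worked example

Simulate a study in which 60% of the causal variants of an HDL-like trait
also drive disease liability, then scan the seven thresholds:

```r
library(prscan)

cfg <- sim_config(n_snps = 3000, n_blocks = 60, n_target = 2000,
                  n_causal = 150, shared_fraction = 0.6,
                  h2_base = 0.4, h2_liability = 0.4, seed = 7)
study <- simulate_study(cfg)

scan <- scan_thresholds(study$hdl, study$target)
fd   <- fdr_adjust(scan$table$assoc_p)
scan$table$q     <- fd$q
scan$table$stars <- star_significance(fd)
scan$table[, c("threshold", "n_snps_used", "assoc_p",
               "r2_nagelkerke", "q", "stars")]
```

```
  threshold n_snps_used  assoc_p r2_nagelkerke        q stars
1     0.001          40 2.36e-18        0.0558 3.72e-18    **
2     0.050          68 3.72e-18        0.0552 3.72e-18    **
3     0.100          80 3.34e-18        0.0553 3.72e-18    **
4     0.200          86 2.63e-18        0.0557 3.72e-18    **
5     0.300          90 2.43e-18        0.0558 3.72e-18    **
6     0.400          96 2.97e-18        0.0555 3.72e-18    **
7     0.500          99 3.04e-18        0.0555 3.72e-18    **
```

Reading the table: 40 clumped SNPs pass the base threshold p_T = 0.001 and
their mean-weighted score separates cases from controls at p ≈ 2e-18
(Nagelkerke R² ≈ 0.056); the SNP count grows with the threshold (the sets
are nested) while the fit stays flat because the simulated signal sits in
the strongly associated SNPs. All seven tests survive FDR at q < 0.01,
and `scan$best_threshold` is `0.001` — the most predictive threshold.

The same scan runs unchanged on a combined base set:

```r
combined <- combine_traits(study$hdl, study$ldl)
scan_pp  <- scan_thresholds(combined[["incHDL+incLDL"]], study$target)
```

For a one-call run of every stage on simulated data (genes → enrichment →
combined traits → PRS scans → pooled FDR → bar-plot report):

```r
res <- run_full(demo_config(out_dir = "demo_run", seed = 1))
res$report$summary_md
```

A thin command-line front end with `simulate | genes | enrich | combine |
prs | fdr | run` subcommands lives at `inst/cli/prscan.R`.

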