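Package: prscan
Title: Polygenic Risk Score Scans for Shared Genetic Etiology with
    Candidate-Gene Network Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether a binary disease trait shares
    genetic etiology with quantitative base traits via clumping-and-
    thresholding polygenic risk scores. Includes GWAS summary-statistic,
    BED and VCF readers with explicit dialect and coordinate rules;
    candidate-gene selection by a p-value threshold and a symmetric
    kilobase window around associated SNPs; right-tailed Fisher's exact
    network enrichment scores; construction of combined base traits by
    effect-sign splitting with harmonic-mean equivalent p-values;
    q-value false discovery rate control with bootstrap selection of the
    lambda tuning parameter and an uncorrected-p floor; and a
    liability-threshold simulator of block-correlated genotypes with
    tunable shared architecture for end-to-end calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
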