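Package: epihub
Title: Covariate-Adjusted SNP-SNP Interaction Scans for Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects pairwise gene-gene (epistatic) interactions affecting a
    quantitative trait with a four-degree-of-freedom nested-model F-test that
    compares a linear model carrying additive and dominance effects of two
    SNPs (plus covariates) against the same model augmented with the four
    additive-by-additive, additive-by-dominance, dominance-by-additive and
    dominance-by-dominance interaction terms. Around the test sit the pieces
    of a complete candidate-gene or single-anchor ("hub") scan: PLINK
    BED/BIM/FAM input and output, call-rate and exact Hardy-Weinberg quality
    control, sliding-window linkage-disequilibrium pruning, a minimum
    genotype-cell-count pair filter, Bonferroni and Benjamini-Hochberg
    multiplicity correction, QQ diagnostics, variance-explained (delta
    R-squared) decomposition, locus-window replication, and a seeded cohort
    simulator for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
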