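Package: preselblup
Title: Genomic Prediction with GWAS-Preselected Variants and Weighted
    Relationship Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how preselecting variants from large
    genome-wide association study (GWAS) meta-analyses affects genomic
    prediction accuracy. Implements fixed-effect phenotype correction,
    genotype quality control (call rate, minor-allele frequency,
    Hardy-Weinberg equilibrium, windowed linkage-disequilibrium pruning),
    ridge-regression BLUP marker-effect estimation, variant ranking and
    top-proportion selection, plain and effect-weighted genomic relationship
    matrices, five BLUP-family prediction models (GBLUP, GFBLUP, TABLUP,
    BLUP|GA, GTBLUP) fitted by restricted maximum likelihood, and repeated
    k-fold cross-validation with paired model comparisons. Includes a
    synthetic-data generator for genotypes with local linkage
    disequilibrium, phenotypes with year/season/sex/farm fixed effects and a
    polygenic plus major-QTL architecture, and multi-cohort meta-analysis
    summary statistics, so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
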