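Package: eqtlnet
Title: Multi-Cohort Lung eQTL Mapping, Meta-Analysis, and Directed Network Key-Driver Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for expression quantitative trait locus (eQTL)
    discovery across multiple cohorts and its integration with disease
    genome-wide association results. Provides genotype quality control
    (call rate and exact Hardy-Weinberg filters), robust Huber covariate
    adjustment of expression, exhaustive single-SNP additive association
    scans with cis/trans classification, permutation-based false discovery
    rate thresholds, inverse-variance fixed- and random-effects
    meta-analysis with Cochran's Q and the DerSimonian-Laird between-study
    variance, a cross-cohort replication rule, eSNP construction and
    GWAS enrichment Q-Q analysis, SNP-to-gene translation, and a directed
    gene-network stage with h-edge neighborhoods, coherent subnetwork
    extraction, key driver analysis, and hypergeometric locus-candidate
    ranking. A seeded synthetic-data generator emulating multi-cohort
    genotype, expression, covariate, GWAS, and regulatory-network structure
    is included for end-to-end exercise and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    metafor,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
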