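Package: perturbscreen
Title: Perturbational Blood Phenotyping: Gating, Genetic and Clinical
    Association, Polygenic Scores and Delayed-Entry Survival Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for perturbation-based blood cell
    phenotyping. Simulates cytometry event clouds, genotypes with
    linkage-disequilibrium block structure, and electronic-health-record
    style outcomes with known ground truth; assigns events to channel
    gates and derives robust evoked-trait parameters (counts, percentages,
    medians, robust standard deviations and coefficients of variation);
    performs phenotype quality control (MAD outlier masking, 2-D ICA
    sample filtering, rank-based inverse-normal transformation, block-wise
    estimation of the number of independent traits); runs covariate-adjusted
    linear association scans with LD clumping and a multi-trait support
    rule; associates traits with binary and continuous clinical endpoints
    under Storey q-value FDR control and ICA projection of the score
    matrix; and builds clumping-and-thresholding polygenic scores evaluated
    with left-truncated Cox proportional-hazards models, Kaplan-Meier
    quartile stratification and random-effects meta-analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    survival,
    metafor,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
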