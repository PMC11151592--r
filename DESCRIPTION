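Package: mbmeth
Title: Microbiome-Methylome Association Screening for Paired Tissue Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links tissue and fecal microbiome composition to host DNA
    methylation in paired tumor/adjacent-normal designs. Provides
    beta-binomial differential-methylation calling from bisulfite count
    files (depth filtering, 500-bp smoothing, DML/DMR thresholds),
    locus-wise penalized-regression association of CpG methylation with
    centered log-ratio transformed taxa (de-sparsified lasso inference,
    complementary-pairs stability selection, FDR intersection, covariate
    filtering), genomic-region enrichment of microbe-associated CpGs
    against a probe background, and cross-cohort random-effects
    meta-analysis of microbial pathway abundances. A synthetic-data
    generator with planted ground truth makes every stage testable
    without access to patient cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan
LinkingTo:
    Rcpp
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
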