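Package: aspuwscan
Title: Adaptive Gene-Based Association Tests for Methylation Data from
    Related Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based association testing of CpG methylation against a
    quantitative trait in family samples. Fits a Gaussian linear mixed null
    model by REML with prespecified variance components (an empirical genetic
    relationship matrix estimated from SNP genotypes and a within-family block
    matrix), extracts the multivariate score vector and its covariance for the
    CpG sites in a gene, and computes weighted sum-of-powered-score (SPUw)
    statistics over a set of powers together with the adaptive minimum-p
    combination (aSPUw), with Monte Carlo p-values from simulated null scores.
    Includes a genome-wide gene-scan driver with Bonferroni adjustment and
    genomic-control diagnostics, plus a synthetic-data generator (pedigrees,
    gene-dropped genotypes, correlated beta-values, mixed-model phenotypes)
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minqa,
    Rcpp,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
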