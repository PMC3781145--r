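Package: epistage
Title: Two-Stage Discovery and Replication of SNP-SNP Interactions in
    Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A pipeline for candidate-gene case-control association studies
    that test for epistasis between biallelic SNPs: per-SNP logistic
    association with genetic-model selection and Hardy-Weinberg checks,
    Multifactor Dimensionality Reduction (MDR) and Model-Based MDR (MB-MDR)
    two-locus interaction detectors with permutation p-values, a
    multi-detector consensus rule, and a replication stage that forces
    discovery-stage risk categories onto an independent series. Includes a
    synthetic genotype simulator with configurable marginal and purely
    epistatic penetrance components for benchmarking the full two-stage
    design.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
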