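Package: crossomics
Title: Cross-Omics Prediction Benchmarking for Paired Microbiome Multi-Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmarking pipeline for predicting one microbial omics layer
    from another (metagenomics, metatranscriptomics, metaproteomics,
    metabolomics) in paired gut-microbiome cohorts. Provides a synthetic
    paired multi-omics generator with planted cross-omics dependencies and
    disease signal, compositional preprocessing (total-sum scaling, zero
    imputation, prevalence/abundance filtering, de-stratification of
    taxon-stratified enzyme features), centered log-ratio, arcsin square
    root and quantile-normal transforms, patient-level stratified
    resampling, per-output-feature elastic-net, random-forest, feed-forward
    network and autoencoder regressors, rank-correlation evaluation with
    core well-predicted feature analyses and enzyme-class enrichment, and a
    downstream inflammatory bowel disease classification task under a
    fairness-controlled downsampling protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    glmnet,
    ranger,
    jsonlite,
    stats,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
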