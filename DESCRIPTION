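Package: microgba
Title: Multi-Cohort Microbiome Analysis and a Gut-Brain Axis Health Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-study case-control metagenomic analysis along the
    microbiota-gut-brain axis: quality-control filters for samples, studies and
    species; community ecology statistics (Shannon diversity, Bray-Curtis and
    Jaccard dissimilarities, principal coordinates analysis, permutation-based
    PERMANOVA); covariate-preserving empirical-Bayes batch correction for
    compositional profiles; per-cohort differential abundance and prevalence
    association with random-effects meta-analytic pooling; a leakage-safe
    nested and leave-one-cohort-out cross-validation framework for microbiome
    disease classifiers; the MGBA-HI per-sample health index centered at the
    Youden-optimal probability threshold; and a tri-criteria consensus for core
    health-associated taxa. Includes a synthetic multi-cohort data generator
    with planted batch and disease effects for ground-truth validation.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    glmnet,
    ranger,
    xgboost
Suggests:
    ape,
    metafor,
    optparse,
    pROC,
    sva,
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
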