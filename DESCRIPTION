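Package: pcgcluster
Title: Unsupervised Random-Forest Clustering of Pharmacy-Based Cost Group Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments insured populations by multimorbidity pattern using only
    pharmacy-based cost group (PCG) indicators from health-insurance claims.
    Implements the unsupervised random-forest dissimilarity (Addcl1 synthetic
    reference, leaf co-membership proximity averaged over forests), metric
    multidimensional scaling by stress majorization, HDBSCAN density clustering
    with condensed-tree persistence, pre-clustering extraction of single-disease
    groups, and Table-style cluster profiling. Ships a synthetic claims-cohort
    generator with configurable population archetypes so the full pipeline is
    testable without proprietary insurer data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    mclust,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
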