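Package: jsseconn
Title: Individual Metabolic Brain Connectomes from FDG-PET via
    Jensen-Shannon Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds individual-level metabolic brain networks from FDG-PET
    volumes by estimating per-region voxel-intensity probability densities
    with kernel density estimation and measuring pairwise similarity with
    the Jensen-Shannon divergence (log base 2). Thresholds each network
    across a sparsity sweep, computes global and nodal graph-theoretic
    metrics with area-under-the-sweep summaries and hub identification, and
    predicts binary surgical outcome (seizure-free versus seizure-recurrence)
    with a linear multi-kernel support vector machine under nested
    leave-one-out cross-validation with t-test feature selection. Includes a
    seeded synthetic-cohort generator (direct region-sample mode and
    phantom-NIfTI mode) so the whole pipeline can be exercised without
    patient data.
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
    igraph,
    jsonlite,
    pROC,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
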