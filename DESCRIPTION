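Package: multiflex
Title: Multilayer Community Structure of Brain-Behavior Correlation Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Jointly clusters edgewise brain-behavior correlation patterns
    across multiple behavioral measures. Computes per-subject functional
    connectivity from parcellated time series, correlates every edge weight
    with every behavioral measure (Spearman), assesses edgewise significance
    by subject-shuffling permutation with Benjamini-Hochberg FDR, transforms
    per-measure correlation matrices into row-profile similarity layers,
    assembles an all-to-all coupled supra-modularity matrix with a uniform
    null model, maximizes multilayer modularity with a generalized Louvain
    heuristic, and builds consensus partitions. Downstream analyses include
    node flexibility, parameter-space characterization (PCA on flexibility,
    partition-landscape degeneracy, seed-based similarity), system-level
    flexibility statistics, and layer-pair community-switching tests with
    permutation nulls. Ships a synthetic-data generator with planted
    community structure and known flexible nodes so the full pipeline is
    testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
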