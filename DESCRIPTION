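Package: gfcband
Title: Graph Frequency Band Connectivity Features for MCI Progression
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A testable reimplementation of a graph signal processing
    pipeline for discriminating stable from progressive mild cognitive
    impairment using resting-state fMRI ROI time series. Provides a
    synthetic cohort generator with planted connectivity differences,
    tapered sliding-window functional connectivity with median
    aggregation, Wilcoxon rank-sum sparsification of the group adjacency,
    graph Fourier transform filtering into low/middle/high graph
    frequency bands, a 100-feature signed-network feature set (global
    graph metrics, minimum spanning tree metrics, triadic balance and
    energy, tendency-to-make-hub, link counts), binary particle swarm and
    simulated annealing wrapper feature selection, and nested
    cross-validated SVM-RBF evaluation with ROC curves and tabular
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
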