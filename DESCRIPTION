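Package: voxgraph
Title: Voxel-Wise Functional Brain Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Density-matched voxel-wise functional connectivity graph analysis.
    Builds binary brain graphs from multi-run BOLD-like time series with the
    S = log(N)/log(K) density-matching rule, computes nodal integration and
    segregation metrics (degree, global and local efficiency, k-core number),
    derives cross-subject overlap and group-difference topology maps with
    metric-conjunction regions of interest, and links regional network metrics
    to behavior and well-being through MANOVA, repeated-measures ANOVA, and
    hierarchical regression.  Includes a synthetic multi-subject cohort
    generator with modular correlation structure, planted group effects,
    nuisance components, and coupled behavioral measures for validating the
    full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    RNifti,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
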