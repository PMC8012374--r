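Package: mranet
Title: Modular Response Analysis of Perturbation Networks with
    Small-Sample Bootstrap Confidence Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers signed, weighted connection coefficients between modules of
    a biological network from steady-state perturbation data (modular response
    analysis, MRA). Estimates confidence intervals for connection coefficients
    and perturbation magnitudes with a parametric bootstrap whose per-cell
    variances come from range-based statistical process control estimators
    designed for very low replicate counts, including an iterative
    gene-population variance estimator with out-of-control exclusion for
    sequencing-style data. Extends inferred networks with non-perturbed genes
    (unidirectional MRA), optimizes perturbation weights, predicts module
    activities and gene expression under combined perturbations, screens gene
    panels for proximity to a reference network, and exports networks as
    GraphML or GML. Ships a synthetic-data generator so that every inference
    step can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
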