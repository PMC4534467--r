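Package: isletgraph
Title: Graph-Theoretic Analysis of Beta-Cell Connectivity in Pancreatic Islets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds contact graphs of insulin-secreting beta cells from
    cell-coordinate tables of pancreatic islets using a neighborhood-radius
    plus shadow-occlusion rule, computes the basic graph measures that
    distinguish type 2 diabetic from control islet architecture (mean degree,
    components per islet, cells per component), estimates same-type and
    cross-type pair distribution functions, simulates stochastic vertex
    rearrangement processes with degree- or component-size-dependent
    relative-likelihood kernels under steric constraints, detects
    measure-equilibria of those processes, compares measures from 3d volumes
    against simulated 2d sections, and generates synthetic islet cohorts so
    the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    grDevices,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
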