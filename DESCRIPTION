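Package: biomorphr
Title: Genotype-Phenotype Map Analysis of Dawkins's Biomorphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exhaustive genotype-phenotype (GP) map analysis of
    Richard Dawkins's biomorphs, a recursive developmental model of 2D
    branching shapes encoded by nine integer genes. Implements the vector
    construction and recursive drawing procedure, coarse-graining of drawings
    onto a binary pixel raster, exhaustive enumeration of neutral set sizes,
    mutational robustness, evolvability and phenotype mutation probabilities,
    an analytic model based on constrained and unconstrained genome positions,
    descriptional complexity estimators (block decomposition and Lempel-Ziv),
    Wright-Fisher population simulations demonstrating bias in the arrival of
    variation, and minimal mutational paths between phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    png,
    jsonlite,
    optparse
Config/testthat/edition: 3
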