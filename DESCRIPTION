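Package: subpathways
Title: Signed Linear Subpathway Decomposition and Permutation Scoring of
    Pathway Topologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes signed, directed pathway topologies (KGML, the KEGG
    XML dialect) into linear root-to-leaf subpathways, extracts the
    leaf-anchored "well-defined" segment of each chain whose case/control
    expression sign changes agree with the activation/repression sign of
    every edge, and scores each segment with a composite statistic
    S = -ln(F_node * F_edge * F_num) combining node-level two-sample t-test
    p-values, a first-order Markov chain of conditional bivariate-normal
    densities over adjacent log2 fold changes, and a path-length
    normalisation from random-graph simulation. Significance is assessed by
    sample-label permutation with Benjamini-Hochberg FDR control. Includes a
    synthetic fixture generator (toy KGML pathways plus two-group expression
    matrices with planted sign-coherent chains) so the full pipeline is
    testable without external downloads.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
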