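Package: homconn
Title: Homological Landscapes of Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Persistent-homology analysis of weighted functional connectivity
    networks. Builds flag (clique) complex filtrations of region-by-region
    correlation matrices, computes persistence diagrams for homological
    dimensions 0-2 by boundary-matrix reduction over GF(2), and compares
    diagrams with the Hausdorff distance on component death values (H0) and
    exact q-Wasserstein distances with partial matchings (H1/H2). Provides
    functional-network partitions, induced sub-connectomes, consolidated
    super-graphs, group-level and individual-level (consensus voting,
    all-to-rest Kullback-Leibler divergence) landscape analyses, and a
    synthetic modular-cohort generator with planted rest-versus-task effects
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
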