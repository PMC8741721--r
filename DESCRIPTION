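Package: sc2fc
Title: Predicting Functional Brain Connectivity and Centrality from
    Structural Connectomes with Message-Passing Graph Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling the structure-function relationship of
    region-level brain connectomes.  Reads and writes structural
    (streamline-count) and functional (Pearson correlation) connectivity
    matrices, computes functional connectivity from multi-session BOLD
    timeseries (per-session z-scoring, 0.01-0.1 Hz zero-phase band-pass,
    session concatenation), thresholds functional networks at the
    critical correlation coefficient, and computes degree, eigenvector
    and PageRank centrality.  Implements an encode-process-decode
    message-passing graph network with analytic backpropagation and Adam
    optimisation for two supervised tasks: edge prediction (structural
    to functional connectivity) and node prediction (structural to
    functional centrality).  Includes mean-level and individual-level
    variance-explained evaluation, virtual-lesion importance analysis,
    and a seeded synthetic connectome cohort generator with a known
    structure-to-function ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    Matrix,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
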