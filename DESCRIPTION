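Package: grugc
Title: Effective Connectivity and Seizure-Network Analysis via Recurrent
    Granger Causality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates directed effective connectivity in multichannel
    intracranial EEG recordings by comparing full and source-excluded
    recurrent (GRU) next-step predictors in the Wiener-Granger sense. The
    resulting causal matrix is row-normalized and thresholded into a
    directed graph on which channels are classified into onset-source,
    propagation-internal and propagation-target roles, scored against an
    expert grouping, and ranked by betweenness and a causal-weighted
    PageRank centrality. A vector-autoregression simulator with known
    directed coupling (optional nonlinear transfer and long lags, plus a
    piecewise seizure-course variant) provides ground truth for
    validating edge recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
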