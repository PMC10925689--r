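Package: seizurenet
Title: Seizure Propagation on Structural Brain Networks with Coupled Epileptor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates networks of coupled Epileptor neural-mass models on a
    weighted, directed structural connectome, detects per-region seizure onset
    from the slow permittivity variable, and classifies propagation as
    localized or widespread. Provides weighted graph measures of the
    epileptogenic zone (degree, eigenvector centrality, inverted-weight
    shortest paths, strongest outgoing weight), two in-silico intervention
    strategies that confine seizures (edge removal with renormalization and
    outgoing-weight reduction with total-strength preservation), a synthetic
    connectome generator with a mirrored two-hemisphere, hippocampus-like
    focus structure, and orchestration of epileptogenic-zone sweeps,
    propagation-regime threshold estimation, intervention evaluation and
    simulated functional connectivity.
License: MIT + file LICENSE
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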