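Package: necknet
Title: Partial-Correlation Network Analysis of Neck Kinematics and Fear of Movement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to study how fear of movement (kinesiophobia) relates to
    neuromuscular and kinematic features of the neck. The package extracts
    range of motion, mean angular velocity, and movement smoothness (spectral
    arc length) from cyclic joint-angle recordings, computes the joint
    reposition error from head-relocation trials, assembles a six-node
    participant feature table, and estimates a regularized Gaussian graphical
    model (graphical lasso with EBIC model selection) over the
    nonparanormal-transformed features. Node centrality (strength, closeness,
    betweenness), bootstrap edge-weight accuracy, case-dropping stability
    (CS coefficients), and sample-size simulations are included, together
    with a synthetic-cohort generator that reproduces the marginal and
    correlation structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    igraph,
    MASS,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
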