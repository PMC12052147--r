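Package: popkernel
Title: Population Rate-to-LFP/EEG Kernels and Their Prediction-Error Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting extracellular brain signals (local field
    potentials and EEG) from population firing rates via spike-to-signal
    kernels, together with an analytical theory for the accuracy of that
    approximation. Generates correlated presynaptic spike-train ensembles
    (Poisson, multiple-interaction processes, a balanced
    integrate-and-fire network), builds single-cell and population kernels
    either from a parametric double-exponential toy model or from passive
    multicompartment simulations of a stylized layer-5 pyramidal-cell
    population coupled to line-source, current-dipole and four-sphere
    volume-conductor forward models, synthesizes ground-truth and
    kernel-approximated signals, and predicts the approximation error from
    kernel heterogeneity and spike-train correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
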