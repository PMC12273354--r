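Package: celltempo
Title: Supervised Pseudotime Inference for Time-Stamped Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers a continuous per-cell pseudotime from time-series
    single-cell data by training one margin classifier per collection time
    point, calibrating the classifier outputs into a probability vector over
    the observed time points, and taking each cell's pseudotime as the
    conditional expectation of its collection time. Includes a bespoke
    kernel soft-margin SVM dual solver, Platt scaling with pairwise
    probability coupling, a nested cross-validation protocol,
    leave-one-time-point-out validation, preprocessing recipes for scRNA-seq
    and scATAC-seq count matrices, simulators for linear and bifurcating
    differentiation trajectories with known ground-truth pseudotime, and the
    evaluation statistics (confusion/accuracy, tie-corrected Kendall rank
    correlation, adjacency statistics with an analytic uniform-error null,
    exact Fisher and Wilcoxon tests, a ridge regression baseline, and
    permutation feature importance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    Rcpp,
    withr,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
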