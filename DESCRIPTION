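Package: molknn
Title: Fast and Interpretable k-Nearest-Neighbor Regression for Molecular Property Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instance-based regression models for scalar molecular properties
    such as electronic binding energies of atmospheric molecular clusters.
    Provides kernel ridge regression with global and extensive
    (sum-of-atomic-kernels) RBF kernels, weighted k-nearest-neighbor
    regression under Euclidean, kernel-induced, and learned Mahalanobis
    distances (Metric Learning for Kernel Regression, MLKR), delta-learning
    between two label levels, leave-one-out tuning of the neighbor count via
    the (k+1)-neighbor shortcut, and neighbor-set quantiles for uncertainty
    estimation. Includes Coulomb-matrix, bag-of-bonds and smeared 2-/3-body
    local descriptors, multi-frame XYZ input/output, a synthetic
    molecular-cluster generator with two correlated label levels for
    end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
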