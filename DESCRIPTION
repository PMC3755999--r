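Package: dmnbnet
Title: Gaussian Bayesian Networks for Structural Covariance of the Default Mode Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns linear-Gaussian Bayesian networks over regional grey-matter
    volumes of eight default-mode-network regions, compares two subject groups
    (normal controls versus Alzheimer's disease) by permutation testing of edge
    coefficients, and classifies subjects by comparing joint probability
    densities under the two fitted networks. Includes exact BIC-optimal
    structure search by dynamic programming, a hill-climbing alternative,
    ROI mean grey-matter volume extraction from NIfTI maps and an
    integer-labelled atlas, and a synthetic-cohort generator based on
    linear-Gaussian structural equation models for simulation studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    RNifti,
    stats,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
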