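Package: efegsim
Title: Forward and Inverse Modeling of Electric Field Encephalography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation study of electric field encephalography (EFEG):
    analytic electric potentials and full electric-field vectors of cortical
    current dipoles in anisotropic multi-shell spherical head models, a
    three-shell boundary-element forward solver with isolated-skull
    correction, synthetic folded cortical source spaces, PCA-based counting
    of uncorrelated detectable signals, and distributed source localization
    (minimum-norm and spatially smooth harmonic-basis estimates) scored by
    geodesic localization error with source-extent correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
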