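Package: cardioROM
Title: Reduced Order Models for Parametrized Cardiac Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Full-order monodomain/Aliev-Panfilov finite-element solver on 2D
    structured grids, together with two families of parametrized reduced order
    models built from its snapshots: a POD-Galerkin baseline with local bases
    and DEIM hyper-reduction, and a deep-learning ROM in which a convolutional
    autoencoder learns a nonlinear trial manifold and a feedforward network
    maps (time, parameters) to latent coordinates. Includes the slab benchmark
    scenarios (ischemic region, S1-S2 re-entry induction, restitution
    variability), error indicators, activation/APD maps, and a small pipeline
    with VTK/CSV/JSON export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
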