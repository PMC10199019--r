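Package: vfpinn
Title: Physics-Informed Reconstruction of 3D Vocal-Fold Dynamics from 2D Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs three-dimensional flow-induced vocal-fold dynamics,
    glottal aerodynamics, and voice acoustics from sparse time-labeled 2D edge
    profiles, as obtained from endoscopic imaging. The inverse engine is a
    hybrid physics-informed neural network: an LSTM encoder-decoder with a
    fully connected head predicts modal coefficients of a finite-element
    eigenmode basis, trained against a loss that combines the residual of the
    modal dynamics equation (with Rayleigh damping, a differentiable 1D
    Bernoulli glottal-flow solver, and a midline penalty contact model) with
    the mismatch between projected and observed 2D profiles. The package also
    provides the forward modal flow-structure-interaction simulator used to
    generate synthetic ground truth, a parameterized two-layer vocal-fold
    mesh generator, acoustic post-processing (SPL and acoustic power from a
    monopole source), and an evaluation workbench.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    signal,
    yaml,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
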