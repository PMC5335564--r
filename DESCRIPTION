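Package: gwbone
Title: Guided-Wave Characterization of Cortical-Bone-Like Waveguides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based analysis of ultrasonic guided waves measured in axial
    transmission on cortical-bone-like waveguides. Provides forward dispersion
    solvers for a transverse-isotropic free plate and for a fluid-solid bilayer
    (a soft-tissue layer resting on the plate), a synthetic-data generator that
    emulates multichannel axial-transmission acquisitions and extracted
    dispersion point clouds, a singular-value-decomposition based
    dispersion-curve extraction chain (response matrix, Norm function,
    bidirectional correction, peak picking, repetition denoising), and a
    genetic-algorithm inversion of the occupancy-rate objective that estimates
    waveguide thickness and stiffness-related bulk wave velocities from noisy,
    incomplete dispersion data. A two-step workflow inverts with the free plate
    model and then checks the estimates inside the bilayer forward model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
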