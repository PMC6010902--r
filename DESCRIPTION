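Package: nanoholo
Title: Simulation and Quantitative Analysis for Hard X-Ray Nanoholotomography Neuroimaging
Version: 0.1.0
Authors@R:
    person("BMC", "Imaging", email = "imaging@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully synthetic re-implementation of the computational
    chain of phase-contrast hard X-ray nanoholotomography of brain tissue:
    generation of phantom tissue volumes with ellipsoidal neuron somata and
    subcellular compartments, forward simulation of multi-distance in-line
    holograms under a cone-beam geometry, contrast-transfer-function phase
    retrieval and filtered back projection, two-step automated neuron
    segmentation (multi-scale Hessian objectness detection followed by
    sparse-field level-set refinement), seeded region growing for subcellular
    structures, and the quantitative metrics used to characterise such data:
    contrast-to-noise ratio from two-Gaussian histogram fits, edge-based
    normalized modulation-transfer-function resolution, object-level detection
    sensitivity, ellipse curvature, translation registration, slice-median
    filtering, and histology-mimicking colour transfer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
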