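Package: pemfdose
Title: Computational Dosimetry for Pulsed Electromagnetic Field Neurostimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Magneto-quasistatic dosimetry for pulsed electromagnetic field
    (PEMF) stimulation of the head. Models a rectangular stimulation coil with
    analytic finite-segment Biot-Savart fields and vector potentials, solves
    the induced electric field and current density on a labeled voxel phantom
    with a scalar-potential finite-difference (SPFD) formulation, reconstructs
    pulsed-signal time courses by harmonic superposition, and analyses
    pre/post-treatment ischemic lesion masks: exposure histograms, coil-frame
    slicing, exposure-conditioned volume ratios and an exponential
    dose-response fit. Includes a synthetic multi-tissue head phantom generator
    with MRI-like rendering, seeded region-growing segmentation, and an
    end-to-end reproducible pipeline for validating dose-response recovery
    against a known ground-truth law.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    RNifti,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
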