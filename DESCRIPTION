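Package: abermat
Title: Aberration-Matrix Computational Adaptive Optics for Angle-Resolved
    Holography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and correction of optical aberrations in angle-resolved
    holographic imaging of thick scattering samples. Builds the aberration
    matrix from tilt-tilt (angular memory effect) correlations of complex
    fields measured under slightly tilted plane-wave illumination, factorizes
    it into incoming and outgoing pupil phase differences by unimodular
    quadratic programming, and integrates the wrapped phase gradients into
    pupil aberration functions. Includes phase-only field correction with
    iterative windowing for deep-tissue scenarios, a CLASS/distortion-matrix
    baseline, gradient-based Rytov diffraction tomography, patchwise
    correction of spatially varying aberrations, quantitative metrics
    (tilt-tilt field correlation, memory-effect range, 3D phase correlation,
    Strehl ratio), and a multi-layer beam-propagation tissue simulator with
    time-gated reflection imaging for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
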