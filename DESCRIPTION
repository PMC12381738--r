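Package: ringfwi
Title: Frequency-Domain Full Waveform Inversion for Ring-Array Ultrasound
    Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sound-speed imaging for multi-row ring-array ultrasound
    tomography by frequency-domain full waveform inversion (FWI).
    Provides a convergent Born-series solver for the heterogeneous
    Helmholtz equation (forward and adjoint) with a sparse direct solver
    as a small-scale oracle, cylindrical-wave acquisition modelling for
    multi-row ring arrays, adjoint-state gradients with per-transmit
    complex source estimation, multi-frequency nonlinear conjugate
    gradient inversion in volumetric 3D and slicewise 2D modes, a
    parametric synthetic breast phantom generator with frequency-domain
    data synthesis and calibrated Gaussian noise, and RMSE/Pearson
    correlation evaluation against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
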