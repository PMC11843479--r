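Package: presir
Title: Phase-Restoring Subpixel Image Registration for Phase-Sensitive
    Fourier-Domain OCT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for correcting displacement-induced phase error in
    phase-sensitive Fourier-domain optical coherence tomography (FD-OCT).
    Implements phase-restoring subpixel image registration (PRESIR), which
    shifts complex-valued OCT images by arbitrary subpixel displacements
    while restoring physically correct phase: axial corrections are applied
    in the spectral (k) domain and lateral corrections in the spatial
    frequency domain. Includes a discrete-scatterer speckle simulator,
    single-step DFT subpixel motion estimation with matrix-multiply
    upsampling, coarse-to-fine volumetric registration, pixel-level and
    Fourier-shift baseline correctors, and phase-stability metrics
    (spatial and temporal OPL standard deviations, SNR-limited phase
    sensitivity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
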