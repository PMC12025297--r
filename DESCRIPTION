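Package: eitrpca
Title: Spike-Noise Removal for Thoracic Electrical Impedance Tomography via
    Robust Principal Component Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cleaning spike-like artifacts from thoracic electrical
    impedance tomography (EIT) boundary-voltage recordings. EIT data matrices
    (measurement channels by time frames) are approximately low rank because
    all channels observe the same respiratory conductivity modulation, while
    electrode-contact and movement artifacts are sparse and large; the package
    separates the two by robust principal component analysis (nuclear norm
    plus l1 penalty) solved with an augmented-Lagrangian ADMM using singular
    value thresholding. It also ships a 16-electrode complete-electrode-model
    finite-element simulator of breathing-modulated thorax phantoms, spike
    injection protocols, GREIT-style linear difference-image reconstruction to
    32 x 32 pixels, functional EIT (standard deviation) imaging, image quality
    metrics and clinical ventilation indices (center of ventilation, global
    inhomogeneity, ventral/dorsal and right/left ratios), temporal low-pass
    and median baseline filters, and experiment drivers that score denoising
    performance against clean ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
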