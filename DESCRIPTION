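Package: mrgqa
Title: Commissioning Toolkit for MR-Guided Brain Radiotherapy: Cine Motion
    Tracking, MR Image Quality, Attenuation, and Setup Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for commissioning a brain treatment package on a low-field
    MR-linac. Implements a seven-step planar cine-MRI head-motion tracking
    pipeline (boundary cropping, contour detection and filling, overlay
    inpainting, crossline-artifact removal, skull-band region-of-interest
    construction, and rigid 2D registration by Pearson-correlation grid
    search), combination of three orthogonal-plane traces into six
    degree-of-freedom head motion with gating checks, ACR large-phantom MR
    image-quality metrics (SNR, percent integral uniformity, percent signal
    ghosting, low-contrast object detectability, geometric accuracy),
    Hounsfield-unit statistics and measured-versus-calculated dose comparison
    arithmetic for immobilization attenuation, mutual-information rigid 3D
    registration for inter-fraction setup variability, and a synthetic
    digital head/ACR phantom generator with ground-truth rigid motion for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
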