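Package: fdpr
Title: Feature-Domain Phase Retrieval for Computational Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Recovers complex optical wavefronts from intensity-only
    measurements by minimizing a loss defined on extracted image features
    (wavelet detail bands, first-order gradients) rather than raw pixels.
    Provides pluggable linear forward models for Fourier ptychographic
    microscopy, lensless coded ptychography and inline holography; Wirtinger
    gradient descent with Adam/YOGI acceleration; a plug-and-play constraint
    block (amplitude thresholds, total-variation and guided-filter denoisers,
    Hessian curvature penalties); classical pixel-domain baselines (GS, ePIE,
    EPRY, mPIE); synthetic phantom and dataset generators emulating LED-array
    illumination, pupil aberrations, vignetting and mixed Poisson-Gaussian
    noise; and image-quality metrics (PSNR, SSIM, noise level, contrast,
    USAF-1951 and Abbe resolution readouts).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
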