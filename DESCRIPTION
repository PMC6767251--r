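Package: silact
Title: Sinogram Inpainting for Ultra-Limited-Angle CT Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the ultra-limited-angle computed tomography
    problem, in which a contiguous block of projection views (often more than
    90 degrees of a 180 degree scan) is missing and classical reconstruction
    fails. Provides a Siddon ray-driven fan/parallel-beam projector with an
    exact adjoint, Ram-Lak filtered back-projection, SART-TV iterative
    reconstruction, a synthetic phantom and paired-sinogram dataset generator,
    and a conditional GAN sinogram-inpainting model (U-Net generator, patch
    discriminator) trained with a joint sinogram-domain and image-domain loss
    in which the image term is computed through the package's own
    differentiable filtered back-projection. Includes image-quality metrics
    (RMSE, NMAD, PSNR, SSIM), an end-to-end pipeline, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
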