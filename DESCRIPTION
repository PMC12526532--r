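Package: aggdeblur
Title: Lightweight Attention-Ghost Adversarial Network for Motion
    Deblurring of Orchard Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for restoring motion-blurred plant and orchard imagery
    with a lightweight generative adversarial network. Provides a
    trajectory-based motion-blur simulator that builds paired sharp/blurred
    datasets from random camera paths, a Ghost-convolution feature-pyramid
    generator with squeeze-and-excitation attention and gated half-instance
    normalization, a relativistic least-squares adversarial training loop,
    a seven-metric full-reference image-quality scorer with blur-severity
    bands, Laplacian-variance blur detection with dynamic pipeline routing,
    and a reporter for detection-metric changes across image-quality
    conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
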