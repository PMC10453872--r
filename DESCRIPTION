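Package: lesiongan
Title: Dermoscopy Image Preprocessing and Semi-Supervised DCGAN Lesion
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Synthesis and binary classification of skin-lesion images with a
    deep convolutional generative adversarial network (DCGAN) whose
    discriminator doubles as an (N+1)-class semi-supervised classifier.
    Provides a dermoscopy preprocessing pipeline (bicubic rescaling, histogram
    equalization, combined unsharp-mask and Gaussian high-pass sharpening,
    CIELAB color balance, noise models, median filtering), image-quality
    metrics (MSE, PSNR, SSIM), the GAN value function and loss closed forms
    with an SGDM training loop, classifier evaluation (confusion matrix,
    balanced accuracy, ROC/AUC), and a seeded synthetic two-class lesion
    generator emulating the ISIC metadata layout so the whole stack is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
SystemRequirements: zlib
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
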