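Package: corneadyn
Title: Corneal Deformation Dynamics from Air-Puff Tonometry Image Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of high-speed cross-sectional image sequences of the
    cornea recorded during an air-puff (non-contact) tonometry examination.
    Detects the outer corneal edge in every frame by column-wise Otsu
    thresholding or Canny edge detection with morphological post-processing,
    separates whole-eyeball displacement from corneal deflection, isolates
    rapidly changing (150-500 Hz) deformations by grayscale morphological
    opening and Fourier band decomposition, derives three dynamic features
    of the eye's response, and assigns one of four deformation classes with
    an unpruned Gini CART decision tree.  A synthetic phantom generator with
    full ground truth supports end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
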