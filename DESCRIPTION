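Package: nlmseg
Title: Two-Dimensional Histogram Image Thresholding with Non-Local Means
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bilevel segmentation of grayscale images by thresholding the joint
    histogram of original and non-local-means filtered gray levels.  The
    threshold vector is selected by minimizing a relative-entropy (minimum
    cross-entropy) criterion over the two-dimensional histogram, so that the
    spatial context captured by the non-local means filter informs the
    threshold choice.  Includes the classical one-dimensional baselines (Otsu,
    Kapur maximum entropy, Li-Lee minimum cross entropy) and the local-mean
    two-dimensional variant for comparison, the misclassification-error
    metric, and a deterministic generator of synthetic two-class images with
    exact ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
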