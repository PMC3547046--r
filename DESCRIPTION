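Package: cellcov
Title: Complex Wavelet Region Covariance Descriptors for Carcinoma
    Cell-Line Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies brightfield microscopy images of cancer cell lines
    from oriented-texture signatures.  Images are decomposed with a
    two-level 2-D dual-tree complex wavelet transform; the six oriented
    subband magnitudes, eight directional difference scores and the
    quarter-resolution intensity image form per-pixel feature maps whose
    region covariance (or correlation) matrices over randomly sampled
    foreground subwindows are vectorized and classified with an RBF-kernel
    support vector machine under per-image majority voting.  Includes
    two-component Gaussian-mixture foreground segmentation with
    morphological refinement, a leave-one-image-per-class cross-validation
    harness, and a synthetic oriented-texture generator with ground-truth
    masks for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
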