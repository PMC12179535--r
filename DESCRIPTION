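Package: hypoxmorph
Title: Weakly Supervised Detection of Hypoxia-Associated Morphology in
    Histology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Weakly supervised analysis of tumor hypoxia from H&E-like
    histology images. Provides a seeded synthetic-cohort generator
    (slide images with class-specific texture and nuclear geometry, an
    expression matrix with a planted hypoxia-signature shift, and
    annotated cell masks), slide tiling with Otsu tissue filtering and
    training-time augmentation, median-split hypoxia metagene scoring
    into weak labels and strata, a multiple-instance-learning
    convolutional classifier with max or gated-attention bag pooling
    trained by stochastic gradient descent, class activation maps, and
    downstream morphometry: gray-level co-occurrence texture features
    and binary shape descriptors with rank-based group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    pROC,
    pracma,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
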