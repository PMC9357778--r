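Package: fuzzymri
Title: Fuzzy C-Means Brain-MRI Segmentation, GLCM Texture Features and a
    PSO-Optimised Extreme Learning Machine
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for a complete brain-tumour image-analysis workflow on
    2-D grayscale images: improved fast-and-robust fuzzy C-means (IFRFCM)
    segmentation working on the gray-level histogram with a neighbourhood
    fuzzy factor, morphological reconstruction preprocessing and adaptive
    Wiener filtering of the fuzzy membership matrix; gray-level
    co-occurrence matrix (GLCM) texture features with regional plane
    splitting; a single-hidden-layer extreme learning machine trained by
    Moore-Penrose pseudoinverse with particle-swarm optimisation of its
    input weights; prevalence-based diagnostic metrics (sensitivity,
    specificity, PPV, NPV, accuracy); and a seeded synthetic phantom
    generator so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
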