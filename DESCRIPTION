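Package: bonetex
Title: Texture-Based Bone Age Estimation from Wrist MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Radiomic texture analysis of coronal wrist magnetic resonance
    images for skeletal bone age estimation in adolescents. Provides region
    of interest extraction from DICOM or PNG scans (pixel or metric units),
    plus/minus three sigma intensity normalization, a 307-feature texture
    descriptor (intensity histogram, gray-level co-occurrence, run-length,
    gradient, autoregressive, Haar wavelet energy, Gabor bank, and gradient
    orientation histogram families), and a regression pipeline that selects
    features by absolute Spearman correlation with age, reduces them by
    principal component analysis, and fits a two-hidden-layer perceptron,
    evaluated by leave-one-out cross-validation. A synthetic cohort
    generator emulates wrist scans with a controlled, monotone age-texture
    relationship so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
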