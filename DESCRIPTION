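Package: pneumotex
Title: Rule-Based Plus Neural-Network Texture Classification of
    Pneumoconiosis Chest-Radiograph ROIs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computer-aided detection pipeline for diffuse pneumoconiosis
    texture in small (32x32 pixel) chest-radiograph regions of interest.
    Implements second-order polynomial trend correction, three enhancement
    branches (radial Hanning/Hamming/Blackman windowing, morphological
    top-hat transform, and a gray-level co-occurrence matrix feature image),
    power-spectrum feature extraction along the dominant radial axes, a
    rule-based classifier at the nodular-pattern frequencies combined with
    three-layer perceptrons, and ROC evaluation with repeated stratified
    train/test splits, curve averaging, and paired t tests.  A synthetic
    lung-texture generator produces labelled ROIs (correlated background,
    vessel-like ridges, rounded and irregular opacities at graded profusion)
    so that the whole scheme can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
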