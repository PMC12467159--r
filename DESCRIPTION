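Package: octatex
Title: Local Texture Descriptors and PCA-Reduced Classification for OCTA
    Vascular Layer Images
Version: 0.1.0
Authors@R:
    person("octatex", "maintainers", email = "octatex@example.org",
           role = c("aut", "cre"))
Description: Dense local texture description of en-face optical coherence
    tomography angiography (OCTA) greyscale images of retinal and choroidal
    vascular layers, and automated binary classification of eyes into
    disease conditions (healthy, dry AMD, wet AMD, secondary CNV).
    Implements generic local binary patterns (LBP), rotation-invariant
    uniform LBP (riu2), and the BRIEF binary descriptor with a
    noise-adaptive threshold, histogram feature vectors per vascular layer,
    layer concatenation, standardization plus principal-component feature
    reduction at a retained-variance threshold, and stratified k-fold
    cross-validated grid search over KNN and SVM classifiers reporting AUC
    and companion metrics. Includes a seeded synthetic vascular-texture
    generator so the full pipeline is testable without clinical data, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    png,
    withr
Config/testthat/edition: 3
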