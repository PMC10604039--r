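Package: mammoCAD
Title: Breast Mass Classification Pipeline with Archimedes Optimization
    and Deep Belief Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale computer-aided diagnosis (CAD) pipeline for
    grayscale mammogram-style images: median-filter impulse denoising,
    U-Net lesion segmentation, SqueezeNet fire-module feature extraction,
    Archimedes Optimization Algorithm (AOA) hyperparameter tuning, and a
    deep belief network (DBN) classifier trained by contrastive-divergence
    pretraining and mean-squared-error backpropagation. Includes a
    synthetic phantom generator with ground-truth masks so the whole
    pipeline is exercisable and testable without external image data,
    plus confusion-matrix evaluation with per-class one-vs-rest metrics
    and stratified train/test splitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
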