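Package: qscreen
Title: Quantum-Inspired Kernel Screening for Parkinson's Disease from
    Smartphone Sensor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end multimodal screening pipeline for Parkinson's
    disease from smartphone-style recordings: feature extraction from
    tri-axial accelerometer gait traces, alternating-finger tapping
    streams, sustained-phonation audio, and demographics;
    random-forest-importance feature selection and weighting; a
    quantum-inspired product kernel that angle-embeds feature differences
    as single-qubit rotations and aggregates measurement probabilities
    with softmax importance weights; a maximum-margin classifier on the
    precomputed Gram matrix; benchmark kernels (Z and ZZ feature maps,
    classical baselines) and exact McNemar comparisons; and a seeded
    class-conditional synthetic-cohort generator so the whole pipeline is
    testable without access to protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    e1071,
    jsonlite,
    kernlab,
    randomForest,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
VignetteBuilder: knitr
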