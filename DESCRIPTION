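Package: autoqsar
Title: Automated QSAR Regression Modeling with Modelability Gating and
    Random-Forest Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An automated pipeline for building and validating QSAR
    (quantitative structure-activity relationship) regression models from
    compound bioactivity data. Curates ChEMBL-style compound-activity
    records (activity-type filtering, desalting, deduplication), computes
    physicochemical descriptors and nine molecular fingerprint types
    through an RDKit backend, scales activities to [0,1] and descriptors
    by train-set min-max, gates datasets on a k-nearest-neighbour
    leave-one-out modelability index (MODI), ranks features by
    random-forest permutation importance averaged over cross-validation
    folds, selects a minimal feature subset by stepwise support-vector
    regression, and validates the final model externally with PVE/RMSE
    and a Euclidean nearest-neighbour applicability-domain check.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
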