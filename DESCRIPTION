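Package: achescreen
Title: Ensemble Pharmacophore Virtual Screening for Acetylcholinesterase
    Inhibitor Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, fully testable implementation of a
    dynamics-aware virtual-screening cascade for acetylcholinesterase
    (AChE) inhibitor discovery. Provides structure-based family
    clustering of inhibitor libraries with Kelley-penalty cluster-count
    selection and IC50-based cluster filtering; statistical extraction
    and diversity selection of receptor conformations from molecular
    dynamics RMSD traces; stable/unstable binding-site zone segmentation
    by smoothed-derivative thresholding; the YN1 ligand-efficiency/IC50
    affinity ranking and the YN2 ensemble pharmacophore screening metric
    with recall-plus-specificity threshold optimization; decoy-balanced
    machine-learning family classifiers; Ellman enzyme-inhibition assay
    analysis (initial velocities, percent inhibition, IC50); and seeded
    synthetic-data generators that emulate every external input so the
    whole cascade runs and validates without commercial docking,
    molecular dynamics, or pharmacophore engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ChemmineR,
    ChemmineOB,
    e1071,
    rpart,
    randomForest,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    pROC,
    bio3d,
    optparse
Config/testthat/edition: 3
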