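Package: lvmda
Title: Synthetic 3D Myocardial Deformation Analysis and Neural-Network
    Classification of Left Ventricular Hypertrophy Etiologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for three-dimensional myocardial deformation analysis on
    dynamic left-ventricular hexahedral meshes. Provides a synthetic dynamic
    LV phantom with analytic ground-truth stretches, Green-Lagrange strain
    computation with directional and principal strains per myocardial layer,
    AHA 16/17-segment feature aggregation, a feed-forward neural-network
    classifier evaluated under stratified 5-fold cross-validation, and
    ROC/AUC machinery with single-marker threshold baselines for the
    discrimination of hypertrophic cardiomyopathy from its mimic states.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
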