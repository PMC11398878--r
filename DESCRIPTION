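Package: evmirna
Title: Plasma Neural-Enriched EV miRNA qPCR Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of plasma neural-enriched extracellular
    vesicle (EV) miRNA qPCR panels: plate-level Cq import, spike-in and
    haemolysis quality control, inter-plate calibrator correction,
    reference-miRNA validation (NormFinder-style stability and pairwise
    variation), Livak 2^-ddCq relative quantification with extreme-outlier
    and invalid-sample filtering, Kruskal-Wallis and Mann-Whitney group
    comparison with signed fold regulation, and three diagnostic classifier
    designs (logistic regression and random forests with iterative feature
    removal) evaluated by confusion-matrix metrics and ROC AUC. Includes a
    synthetic cohort generator with known ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
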