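Package: fibrilthread
Title: Threading Peptide Pairs onto Cross-Beta Fibril Templates to
    Predict Amyloid Cross-Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts homo- and cross-aggregation of amyloid-forming
    peptides by threading a pair of query sequences onto the backbone of
    a stacked cross-beta fibril template, building a coarse-grained
    heterotetramer (two chains of each peptide), and scoring the model
    with a distance-binned residue-pair statistical potential normalized
    by peptide length (the ndope score; lower is more stable).  Includes
    ROC-based threshold calibration, a cross-validated evaluation
    protocol (accuracy, sensitivity, specificity, F1, MCC, AUC,
    Mann-Whitney comparison of score distributions), sliding-window
    fragment scanning to localize interacting regions in longer
    proteins, and a synthetic-fixture generator (idealized fibril
    templates, potential tables, labeled benchmark pair sets) so the
    whole pipeline can be exercised without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
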