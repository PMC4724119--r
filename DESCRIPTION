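Package: spliceRF
Title: Donor Splice-Site Prediction with Di-Nucleotide Association Encoding
    and Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts donor (5') splice sites in genomic sequences. Fixed-length
    GT-anchored sequence windows are encoded into numeric vectors through
    adjacent di-nucleotide association scores (three log2 scoring procedures
    against random or position-weight-matrix expected frequencies), and a
    difference scoring matrix contrasting true and false splice sites. Encoded
    vectors are classified with a random forest, with out-of-bag tuning of
    mtry and ntree, vote-ratio class cutoffs for imbalanced data, margin
    diagnostics, stratified k-fold cross-validation, weighted confusion
    matrices, seven performance metrics, and exact Mann-Whitney fold
    comparisons. Includes a synthetic GT-window generator with controllable
    positional consensus and first-order dependency, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    randomForest,
    e1071,
    nnet,
    class,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
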