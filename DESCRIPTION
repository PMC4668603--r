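Package: NRCascade
Title: Two-Level Prediction of Nuclear Receptors and Their Subfamilies
    from Protein Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequence-based classification of nuclear receptor (NR)
    proteins. Encodes protein sequences as amino acid composition (AAC,
    20-d), conjoint triad features over a seven-class reduced alphabet
    (CTF, 343-d), and chaos game representation segment frequencies on a
    12-sided polygon (CGR, 24-d), plus all concatenations of the three
    blocks. A two-level cascade of RBF-kernel support vector machines
    first separates NRs from non-NRs and then assigns predicted NRs to
    one of the eight NucleaRDB subfamilies (NR1-NR8). Includes the full
    evaluation protocol (stratified k-fold cross-validation, jackknife,
    sensitivity/specificity/accuracy/MCC, ROC/AUC), Wilcoxon rank-sum
    feature significance ranking with top-k selection and ablation, a
    synthetic benchmark generator with planted triad biases, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Biostrings,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
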