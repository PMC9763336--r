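Package: acplearn
Title: Anticancer Peptide Classification with Bidirectional LSTM Networks
    and Multi-Feature Sequence Encodings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for predicting anticancer peptides (ACPs) from amino-acid
    sequence. Peptides are encoded as fixed-size numeric matrices combining a
    one-hot binary profile with standardized quantitative physicochemical
    properties and one-hot qualitative property categories, and classified with
    bidirectional LSTM networks, optionally extended with additive self-attention
    over residue positions and attention pooling. Includes stratified
    cross-validation and MCC-driven grid search, confusion-matrix metrics and ROC
    AUC, permutation Shapley-value attributions with per-channel importance
    ranking, PCA projection of learned features, a sequence-identity redundancy
    filter for test sets, and a synthetic benchmark generator with planted
    compositional signal so the full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
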