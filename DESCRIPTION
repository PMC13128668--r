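Package: prohl
Title: Sequence-Based Classification of Short-Lived and Long-Lived Bacterial Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies bacterial proteins as short-lived (half-life below one
    hour) or long-lived from amino-acid sequence alone. Fuses three views of a
    protein: residue-level embeddings projected to a fixed-length vector by a
    small convolutional network, sequence-level embeddings reduced by principal
    component analysis, and four families of physicochemical descriptors
    (gapped k-mer pair composition, dipeptide deviation from expected mean,
    composition/transition/distribution, and sequence-order descriptors)
    filtered by per-feature ANOVA. Includes greedy identity-based redundancy
    reduction of training sets, MCC-driven grid-search model selection with
    stratified cross-validation, a leave-one-group-out descriptor ablation
    harness, and a synthetic labelled-proteome generator with plantable degron
    motifs for end-to-end validation without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
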