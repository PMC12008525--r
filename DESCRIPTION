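Package: rowfold
Title: RNA Secondary Structure Prediction as Row-Wise Multi-Class Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts RNA secondary structure by casting the L x L base-pair
    contact matrix as L parallel L-class classifications. Unpaired bases are
    labelled on the matrix diagonal so that every row of the label is one-hot,
    a weighted row-wise cross-entropy handles the paired/unpaired imbalance,
    and a decoder (row argmax, Hadamard product with the transpose, sharp-loop
    mask) yields structurally valid predictions - symmetric, at most one
    partner per base, no sharp loops, pseudoknots allowed - without iterative
    post-processing. Includes a Transformer-encoder + U-Net scoring network
    trained with hand-derived gradients, sequence data-augmentation operators
    acting only on unpaired bases, a knowledge-merge pipeline that labels
    random sequences with a built-in Nussinov folder (or any external folding
    program), F1 and interaction-network-fidelity evaluation, and readers and
    writers for FASTA, CT and pseudoknot-tiered dot-bracket formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
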