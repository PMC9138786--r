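Package: DDIfuse
Title: Multi-Channel Feature Fusion for Drug-Drug Interaction Prediction
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts drug-drug interactions (DDIs) by fusing three per-drug
    feature channels: a chemical-sequence channel built from CBOW token
    embeddings of SMILES strings, a network channel built by hierarchical
    graph coarsening with second-order LINE embedding of the known-interaction
    graph, and a biological-function channel built by similarity network
    fusion (SNF) of per-receptor-type profile similarities. The channels are
    integrated per drug with scaled dot-product attention and classified by a
    feed-forward network trained end-to-end with binary cross-entropy.
    Includes the full evaluation protocol (balanced negative sampling,
    70/20/10 split or 5-fold cross-validation, Acc/Prec/Sen/F1/MCC/AUC/AUPR),
    candidate ranking, and a synthetic planted-community data generator so
    every stage runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
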