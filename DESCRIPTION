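Package: psnfuse
Title: Patient Similarity Network Fusion for Multi-Omics Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Network-based integration of multi-omics data for binary
    clinical-outcome prediction. Builds scale-free patient similarity
    networks (PSN) per omics type by soft-thresholding inter-patient
    Pearson correlations, extracts node centrality and module-membership
    features, fuses omics either at the network level (similarity network
    fusion) or at the feature level, classifies with a small feed-forward
    neural network trained with class-weighted cross-entropy or with
    recursive-feature-elimination-wrapped linear estimators, and ranks
    features by Integrated Gradients attribution. Includes a synthetic
    multi-omics generator with known ground truth, a univariate rank-test
    prefilter with Benjamini-Hochberg correction, and nested
    cross-validation for leakage-free evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    e1071,
    rpart,
    randomForest,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
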