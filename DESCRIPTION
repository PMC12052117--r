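Package: gliosemi
Title: Semi-Supervised Radiomics Pipeline for IDH1 Mutation Status Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end semi-supervised pipeline for predicting binary tumor
    genotype (IDH1 mutant versus wild type) from multi-sequence brain MRI
    volumes. Computes gray-level co-occurrence (GLCM) and run-length (GLRLM)
    texture features, screens them by independent two-sample t-tests, removes
    redundancy by rough-set positive-region attribute reduction, builds
    per-feature Youden-index threshold rules to pseudo-label unlabeled
    patients, tunes the pseudo-label loss weight with sand cat swarm
    optimization (SCSO), and trains a U-Net-style convolutional autoencoder
    feature extractor followed by a convolutional-recurrent (LSTM) sequence
    classifier on the weighted semi-supervised objective. Includes a synthetic
    phantom-cohort generator so every stage is exercisable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
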