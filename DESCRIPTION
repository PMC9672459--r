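Package: phageprom
Title: Two-Layer Promoter Identification and Classification for Phage Genomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identification of promoters in bacteriophage genome sequences and
    classification of identified promoters as phage- or host-recognized, using
    a two-layer cascade of compact one-dimensional convolutional neural
    networks trained on 99-bp sequences. Includes a hard-negative generator
    that partially shuffles promoter sequences in blocks so that 35-40% of
    positions remain conserved, ten DNA feature-encoding schemes (one-hot,
    nucleotide chemical properties, k-mer composition, PseEIIP, PseDNC,
    PseKNC, PCPseDNC, PCPseTNC, dinucleotide auto-cross covariance, Moran
    autocorrelation), a uniform interface over ten baseline machine-learning
    classifiers, evaluation metrics (accuracy, sensitivity, specificity,
    Matthews correlation coefficient, precision, recall, ROC/AUROC) with
    stratified k-fold cross-validation, and a synthetic-data generator for
    end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    seqinr,
    e1071,
    rpart,
    nnet,
    class,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
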