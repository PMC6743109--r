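Package: kmerCNN
Title: Classification of lncRNA and mRNA Sequences from k-mer Frequency
    Matrices with a Convolutional Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discriminates long non-coding RNA (lncRNA) from messenger RNA
    (mRNA) transcripts using only sliding-window k-mer composition.
    Per-sequence k-mer frequency vectors (canonical A,T,C,G digit order,
    per-k normalization) are laid out as small 2-D frequency matrices and
    classified by a two-convolutional-layer neural network trained with
    Adadelta; large k-mer vocabularies can first be screened by
    relative-entropy (Kullback-Leibler) ranking with a cumulative
    information-ratio cutoff.  Includes framework-independent reference
    implementations of the forward-pass tensor primitives (convolution,
    zero padding, max pooling, softmax), random forest / logistic
    regression / decision tree / SVM baselines on the same features,
    confusion-matrix and ROC/AUC evaluation, and a first-order Markov
    simulator producing labeled two-class sequence corpora for end-to-end
    testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    glmnet,
    jsonlite,
    methods,
    randomForest,
    rpart,
    e1071,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
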