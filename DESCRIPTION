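Package: countLDA
Title: Count-Model Discriminant Analysis for RNA-seq Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discriminant analysis of RNA-seq count matrices under four
    nested count models: Poisson (PLDA), negative binomial (NBLDA),
    zero-inflated Poisson (ZIPLDA) and zero-inflated negative binomial
    (ZINBLDA) linear discriminant analysis. Provides maximum-likelihood
    and posterior-mean parameter estimators (total-count size factors,
    gene abundances, class-difference factors, per-gene dispersion by
    bounded likelihood maximisation, and a logistic model linking the
    excess-zero probability to sequencing depth and gene mean), a
    negative-binomial simulation engine for benchmarking the classifiers
    across sample size, dispersion and zero-inflation regimes,
    between/within sum-of-squares gene screening, and a decision-tree /
    random-forest meta-selector that recommends the classifier expected
    to minimise misclassification for a new dataset from its estimated
    attributes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    rpart,
    randomForest,
    glmnet,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
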