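Package: hordcnn
Title: Surrogate-Optimized 1-D CNN Classification of Gene Expression with
    Binary PSO Gene Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reusable toolkit for classifying leukemia subtypes from
    microarray gene-expression profiles. Provides digit-scaling and min-max
    normalization with leak-free train/test records, binary particle swarm
    optimization (BPSO) wrapper feature selection over gene columns, a cubic
    radial-basis-function interpolation surrogate with linear polynomial
    tail, a HORD-style surrogate optimizer (Latin-hypercube initial design,
    dynamic coordinate search with a logarithmically decaying perturbation
    probability, weighted candidate scoring), a configurable 1-D
    convolutional neural network classifier trained by backpropagation with
    Adam, one-vs-rest confusion-matrix metrics with ROC/AUC, and a
    synthetic-data generator emulating the classic 72-sample x 7129-gene
    leukemia expression layout so the whole pipeline is exercisable without
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
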