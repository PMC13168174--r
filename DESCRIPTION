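Package: yieldclass
Title: Classification-Based Genomic Prediction for Early-Stage Yield Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for advancing or discarding breeding lines in early-stage,
    sparsely tested multi-environment yield trials. Implements marker quality
    control, iterative random-forest imputation and the VanRaden genomic
    relationship matrix; an EM-REML genomic mixed model with a factor-analytic
    (order 1) genotype-by-location structure that predicts genotype performance
    in observed and unobserved environments; a check-referenced selection index
    (MSI) with three-class yield categorisation; repeated stratified
    cross-validation of multinomial elastic-net and random-forest classifiers
    on SNP markers; a confusion-matrix evaluation suite with one-vs-rest
    macro metrics, misclassification-severity analysis and probability-threshold
    advancement decisions; and a synthetic-data generator emulating a soybean
    preliminary yield trial so the whole pipeline is testable without
    proprietary data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    caret,
    vcfR,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
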