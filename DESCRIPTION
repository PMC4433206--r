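Package: edtar
Title: Expert-Guided Transformation of DNA-Index Cytometry and Oral
    Cancer Risk Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative risk stratification of oral lesions from
    exfoliative-cytology DNA-index (DI) measurements.  Each case's DI
    distribution is decomposed into diploid, tetraploid and aneuploid
    cell populations by kernel-density peak identification and
    sequential mirror extraction; the aneuploid signal is amplified by
    rule-based re-weighting of the population ratios; the amplified
    mixture is reconstructed as a fixed 16-bin density feature vector
    over DI [0, 8]; and a radial-kernel support vector machine turns the
    features into a calibrated Oral Cancer Risk Index (OCRI) in [0, 1].
    Includes a synthetic DNA-image-cytometry generator (three-component
    Gaussian mixtures with normal / leukoplakia / carcinoma case
    profiles) so every stage is testable without patient data, the
    conventional qualitative cytology call (aneuploid cell counting) as
    a baseline, and a six-model resampling benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    kernlab,
    caret,
    pROC,
    randomForest,
    glmnet,
    nnet,
    rpart,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
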