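Package: audseg
Title: Audience Segmentation of Survey Data with Response-Style Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A reproducible pipeline for attitudinal audience segmentation of
    Likert-type survey data. Provides respondent-level quality screening
    (straight-lining and extreme-acquiescence removal), dual-mode
    standardization (question-level z-scaling and respondent-level ipsative
    scaling to neutralise acquiescence bias), exploratory factor analysis with
    Cronbach-alpha reliability refinement, a hybrid segmentation engine
    (stability-checked k-means, classical multidimensional scaling, polar
    sectoring, central-group handling, nearest-centroid refinement, bootstrap
    move thresholds and quadratic-discriminant allocation of booster samples),
    market-research profile tables with pairwise significance letters, and
    predictive-validity comparison of segments against demographics via Type
    III ANOVA partial eta-squared and logistic Wald statistics. A synthetic
    survey generator with known latent segments and response styles supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    mclust,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
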