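Package: brainproxy
Title: Proxy Measures of Age, Fluid Intelligence, and Neuroticism from
    Brain and Sociodemographic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds machine-learning proxy measures of brain age, fluid
    intelligence, and neuroticism from image-derived phenotypes,
    tangent-space functional-connectivity embeddings, and block-structured
    sociodemographic variables, and validates the resulting out-of-sample
    proxies against health-related habits. Provides Ledoit-Wolf shrinkage
    covariance estimation, affine-invariant tangent-space embedding,
    Monte-Carlo cross-validation with CV-bagging of random-forest models,
    quadratic deconfounding transferred from validation to held-out data,
    permutation and paired-swap model comparison tests, non-parametric
    bootstrap intervals, parametric-bootstrap inference for standardized
    habit regressions, and a synthetic-cohort generator with recorded
    ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    jsonlite,
    ranger,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
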