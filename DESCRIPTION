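Package: adtep
Title: Adversarial Deep Treatment Effect Prediction from Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binary treatment outcomes from tabular electronic
    health record (EHR) cohorts with an adversarial dual-autoencoder model
    (ADTEP). Two autoencoders learn latent representations of patient
    features and of administered treatments; an outcome-conditioned
    generator and a discriminator couple the two representations through an
    adversarial objective, and a logistic layer over the concatenated latent
    codes predicts the outcome. The package also provides the
    non-adversarial ablation (DTEP), an ablation-based per-treatment
    relevance statistic, logistic-regression and support-vector-machine
    baselines, repeated stratified cross-validation with AUC and threshold
    metrics, baseline-characteristics tables (chi-squared and Mann-Whitney
    tests), EHR feature encoding with a three-level normal-range scheme,
    and a synthetic cohort simulator with confounded treatment assignment
    and known planted effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    glmnet,
    e1071
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
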