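Package: frailmix
Title: Factor Mixture Models for the Structural Validity of the Frailty Phenotype
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether the five-component frailty phenotype
    (unintentional weight loss, exhaustion, weakness, slowness, low physical
    activity) behaves as a syndrome, as a categorical rendering of a continuous
    process, or as a homogeneous population. Provides a seeded synthetic-cohort
    generator with a left-censored gait-speed item and a two-part weight-loss
    item; sex-, height- and BMI-stratified quintile cut points and the 0/1-2/3+
    frailty index; latent class analysis of dichotomized components; maximum
    likelihood estimation of factor mixture models under measurement-invariance
    constraints (strict/strong/weak/none, equal or unequal variances) via EM
    with Gauss-Hermite quadrature; model comparison with BIC differences and
    the parametric bootstrap likelihood-ratio test; Monte Carlo acceptability
    diagnostics (bias, standard-error bias, coverage, power); and an
    eight-step pipeline that checks component ordering across classes and
    emits a syndromic / categorical-approximation / homogeneous verdict.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
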