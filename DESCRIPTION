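Package: spcdm
Title: Saturated Polytomous Cognitive Diagnosis Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cognitive diagnosis modelling for attributes with two or more
    ordered mastery levels. Implements the saturated polytomous cognitive
    diagnosis model (sp-CDM) under identity, logit and log link functions,
    together with its reduced special cases (polytomous G-DINA, fully
    additive, minimum/maximum level, conjunctive and disjunctive models)
    via constrained design matrices. Provides marginal maximum likelihood
    estimation by an EM algorithm with optional monotonicity constraints,
    empirical cross-product standard errors, MAP/EAP examinee
    classification, model fit statistics (deviance, AIC, BIC), a Monte
    Carlo simulation engine with item-quality-controlled generating
    parameters, and evaluation metrics (bias, RMSE, attribute and vector
    classification rates, posterior-weighted RMSD between fitted models).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
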