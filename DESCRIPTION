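Package: admito
Title: Bayesian Diet and Mitochondrial-Dynamics Risk Model for Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A seeded Monte-Carlo cohort simulator over a signed influence
    graph linking diet type, mitochondrial fission/fusion biomarkers
    (DRP1, FIS1, OPA1, MFN1, MFN2) and lifestyle risk factors to the
    probability of prodromal or mixed Alzheimer's disease progression.
    Includes the supporting Bayesian machinery (uniform likelihood, Pareto
    conjugate prior with closed-form updating, discrete posterior
    normalisation, Monte-Carlo conditional-probability estimation with
    binomial Monte-Carlo error), a deterministic case evaluator that maps an
    evidence pattern to a risk probability, cohort CSV input/output with a
    fixed schema, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
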