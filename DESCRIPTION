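Package: metacogr
Title: Signal-Detection Modelling of Metacognition and Transdiagnostic Symptom Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking two-alternative forced-choice decision behaviour with
    confidence ratings to dimensions of psychopathology. Implements the extended
    signal-detection (meta-d') observer model with maximum-likelihood and MCMC fitting,
    hierarchical Bayesian estimation of metacognitive efficiency (Mratio) with
    highest-density-interval inference, confidence-criterion (metacognitive bias)
    quantification, transdiagnostic factor scoring from questionnaire items, data-quality
    exclusion rules, standardized multiple regression with collinearity diagnostics,
    noncentral-F power analysis, and a synthetic-cohort generator with planted effects
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
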