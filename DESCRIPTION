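Package: dcemix
Title: Discrete Choice Experiment Design, Simulation, and Mixed-Logit Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stated-preference discrete choice experiments (DCEs) in
    health policy: attribute-space definition, blocked balanced-overlap design
    construction with sample-size rules, simulation of respondent panels and
    choices from a random-coefficients utility model, estimation of mixed-logit
    (MXL) and mixed-mixed multinomial logit (MMML, a finite mixture of
    class-specific mixed logits with covariate-driven class membership) models
    by maximum simulated likelihood with scrambled Halton draws, BIC class
    selection, and willingness-to-pay reporting. Defaults emulate a discrete
    choice experiment on preferences for COVID-19 nonpharmaceutical
    interventions in Singapore.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
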