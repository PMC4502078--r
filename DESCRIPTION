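Package: eqvas
Title: EQ-5D-3L Health-State Valuation from Orthogonal VAS Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating EQ-5D-3L utility tariffs from visual analogue
    scale (VAS) valuation studies built on orthogonal-array valuation subsets.
    Provides the 243-state EQ-5D-3L state space with dummy, presence and count
    encodings; construction and validation of 18-row orthogonal valuation sets
    related by a modulo-3 generator; VAS rescaling onto the dead/full-health
    scale at the individual and aggregate level; ordinary least-squares utility
    models with and without a constant term and with N-term or count-term
    extensions, fitted equivalently from respondent-level records or weighted
    state means; a model evaluation battery (mean absolute error, residual
    exceedance rates, within- and out-of-sample correlation, holdout error,
    internal validity); and a synthetic respondent generator for parameter
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
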