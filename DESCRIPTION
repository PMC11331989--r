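Package: dyadarc
Title: Dyadic Affect and Aggression Dynamics for Competitive Reaction Time Sessions
Version: 0.1.0
Authors@R: person("dyadarc", "maintainers", email = "maintainers@dyadarc.invalid",
    role = c("aut", "cre"))
Description: Analysis pipeline for face-to-face competitive reaction time
    sessions played by dyads: converts automated facial action coding output
    into prototypic positive/negative emotion intensities, joins them to trial
    logs, classifies high-affect trials, compresses win streaks into an
    alternating-winner series, quantifies escalation/retaliation and blast
    matching, fits longitudinal actor-partner interdependence models and a
    forced-break mediation model, and provides the rank-based and Bayesian
    inferential primitives the analysis relies on. Includes a seeded generative
    simulator of whole sessions so every stage is testable without external
    data, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
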