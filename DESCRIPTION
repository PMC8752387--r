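Package: ascotcarer
Title: Preference-Weight Valuation for the ASCOT-Carer Instrument
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating and applying preference weights (a value set)
    for the seven-domain ASCOT-Carer instrument, which measures the social
    care-related quality of life of informal caregivers. Implements the full
    valuation pipeline: balanced fractional-factorial profile designs for
    profile-case best-worst scaling (BWS), the exploded sequential
    best/worst/second-best/second-worst choice structure, conditional-logit and
    panel mixed-logit estimation by maximum simulated likelihood with scrambled
    Halton draws, composite time trade-off (cTTO) scoring with conventional and
    lead-time branches, linear anchoring of latent BWS scores onto TTO values,
    tariff construction and utility scoring of ASCOT-Carer states. A synthetic
    respondent simulator with Gumbel choice noise and normally distributed
    preference heterogeneity makes the whole pipeline testable end to end, and
    the published Japanese valuation tables ship as packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
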