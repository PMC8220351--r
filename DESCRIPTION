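Package: cfstrans
Title: Clinical Frailty Scale Scoring, State Transitions and Care Utilisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for frailty analyses of longitudinal ageing cohorts based on
    the Clinical Frailty Scale (CFS). Scores CFS categories 1-9 from six
    questionnaire-derived items via a configurable classification tree,
    collapses categories into fit/vulnerable/frail analysis states, estimates
    2-year state-transition probabilities from interval-censored panel data
    using a continuous-time multi-state Markov model with an absorbing death
    state (with parametric-bootstrap confidence intervals), tabulates
    wave-to-wave flow counts for alluvial displays, and computes
    survey-weighted summaries of health and social care utilisation by CFS
    category. Includes a synthetic cohort generator emulating a biennial
    five-wave panel of adults aged 65 and over with mortality, attrition and
    category-conditional utilisation, so the full pipeline can be exercised
    and validated without access-restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
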