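Package: crctriage
Title: Microsimulation of FIT and Risk-Score Triage for Symptomatic Colorectal Cancer Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual patient-level simulation for evaluating the
    cost-effectiveness of referral triage strategies in symptomatic
    primary-care populations tested with the faecal immunochemical test
    (FIT). Generates correlated synthetic populations from aggregate
    quantile data via a Gaussian copula, stratifies patients by FIT value
    or a multivariable colorectal cancer risk score at arbitrary
    thresholds, simulates the short-term diagnostic pathway (referral
    uptake, colonoscopy/CT colonography, diagnostic delay, emergency
    presentation) and a lifetime annual-cycle Markov model of cancer
    stage progression and survival, and computes costs, QALYs,
    incremental net monetary benefit, threshold sweeps, subgroup results,
    scenario analyses and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
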