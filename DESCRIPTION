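Package: scoretodoor
Title: Score-to-Door Time Analysis for Deteriorating Ward Patients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the interval between the onset of sustained
    physiological derangement on a hospital ward and admission to critical care
    ("Score to Door" time). Computes National Early Warning Scores (NEWS and
    NEWS2 Scale 1) from raw vital-sign observations via declarative band
    tables, derives the sustained-high-NEWS analysis cohort from timestamped
    ward observations and admission events with a full exclusion ledger, and
    fits the associated descriptive comparisons, stepwise logistic mortality
    models and log-linear length-of-stay models with bias-corrected
    accelerated (BCa) bootstrap confidence intervals. A synthetic ward
    electronic-health-record generator with controllable effect sizes makes
    the whole pipeline testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    boot,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
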