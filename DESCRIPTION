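Package: dapdose
Title: Bayesian Therapeutic Drug Monitoring and Precision Dosing for Daptomycin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-informed precision dosing engine for daptomycin in patients
    with bone and joint infection. Implements a two-compartment intravenous
    infusion pharmacokinetic model with closed-form concentration and
    steady-state exposure computation, two individual Bayesian estimators (a
    nonparametric discrete-posterior engine and a parametric maximum a
    posteriori engine), AUC- and trough-targeted dose optimization, the
    validation and agreement statistics used to compare precision-dosing
    tools (mean error, mean absolute percent error, Bland-Altman analysis
    with regression-based limits of agreement, rank tests, target-attainment
    fractions), and a synthetic sparse-sampling TDM cohort generator with
    NONMEM-style event-record input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
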