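Package: mcat4pl
Title: Multidimensional Four-Parameter Logistic IRT Calibration and
    Computerized Adaptive Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Confirmatory multidimensional item response theory with the
    four-parameter logistic (4PL) model for dichotomous items: marginal
    maximum likelihood calibration with multi-start estimation,
    limited-information fit statistics (M2, RMSEA, SRMSR, TLI, CFI),
    maximum a posteriori (MAP) trait scoring with per-dimension standard
    errors and reliabilities, information-based adaptive item selection
    (determinant, trace, A-, weighted and eigenvalue rules plus
    posterior-weighted variants), staged standard-error stopping rules
    with a stability criterion, and a Monte Carlo simulation framework
    for tuning starting items and selection rules in multidimensional
    computerized adaptive tests, as used in early-literacy screening.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
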