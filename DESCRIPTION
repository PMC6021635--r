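Package: polybtdm
Title: AUC-Guided Precision Dosing of Polymyxin B by Adaptive Feedback Control
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Individualizes polymyxin B dosing with an adaptive feedback
    control loop: closed-form two-compartment infusion kinetics under a
    lognormal population pharmacokinetic model, maximum a posteriori (MAP)
    Bayesian estimation of individual clearance from sparse day-1 plasma
    samples, dose personalization to a steady-state AUC(0-24) target window
    of 50-100 mg.h/L, Monte-Carlo evaluation of sparse sampling strategies,
    and the weighted exposure-nephrotoxicity meta-regression defining the
    window's upper bound.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
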