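Package: hrnv
Title: Heart Rate n-Variability Analysis and Cross-Validated Mortality Modelling
Version: 0.1.0
Authors@R: person("HRnV", "Maintainers", email = "maintainers@hrnv.dev", role = c("aut", "cre"))
Description: Tools for heart rate n-variability (HRnV) analysis of short
    single-lead ECG recordings and RR-interval tachograms, and for the
    downstream clinical risk-modelling workflow built on those measures.
    Includes an integral-pulse-frequency-modulation (IPFM) tachogram and
    ECG simulator with a matched two-group cohort generator; QRS detection
    and construction of combined-interval RRnI / RRnIm sequences; the full
    time-domain, Lomb-Scargle frequency-domain, and nonlinear (Poincare,
    sample/approximate entropy, detrended fluctuation analysis) parameter
    suite including the NN50n / pNN50n measures; baseline two-group cohort
    comparison with normality-gated tests and median imputation; a
    univariable screen, collinearity pruning and backward stepwise logistic
    regression pipeline; and 10-fold cross-validated ROC/AUC evaluation
    against NEWS, MEWS and qSOFA early-warning scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
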