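Package: equiwtp
Title: Double-Bounded Dichotomous-Choice Willingness-to-Pay Estimation for
    Equine Care Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contingent-valuation surveys of equine owners, boarders
    and leasers that elicit willingness to pay (WTP) for essential care with a
    double-bounded dichotomous-choice design.  Provides the randomized bid
    schedule (an initial 10 percent cost increase with an 11-20 percent or
    1-9 percent follow-up), the mapping from yes/no response sequences to
    censored WTP intervals, maximum-likelihood estimation of the
    interval-censored Gaussian regression with sandwich (robust) covariance
    and Wald tests, delta-method mean-WTP prediction at covariate means, and
    a calibrated synthetic-survey generator so the whole pipeline can be
    exercised and validated end to end without access to raw survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
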