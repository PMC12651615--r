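Package: dsurprisal
Title: Prospective Bayesian Surprisal for Daily-Diary Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Day-by-day Bayesian estimation of surprisal (self-information)
    for daily-diary exposure variables of three measurement types: binary
    exposures (Beta-Bernoulli), heaped continuous sleep duration
    (known-variance Normal mean updating with half-integer discretisation
    and truncation at zero), and zero-inflated right-skewed stress
    intensities (hurdle-Gamma refit by posterior sampling at each day).
    Supports uninformative and leave-one-out empirical prior conditions,
    a static full-record empirical surprisal benchmark, per-day cohort
    summaries of expectations and dynamic-minus-static surprisal
    differences, and a synthetic diary-cohort generator for testing and
    demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fitdistrplus,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
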