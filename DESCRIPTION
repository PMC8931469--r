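Package: ovutherm
Title: Temperature-Based Ovulation Confirmation, Prediction, and Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for confirming and predicting ovulation from nightly
    body-temperature series. Implements the classical "three over six"
    basal body temperature rule, a moving-window shift detector, and a
    robust exponentially-weighted ("spring-loaded beam" style) trend
    detector; a median-based predictor of the ovulation day in a newly
    started cycle from up to twelve previous ovulatory cycles; and a
    complete evaluation framework (signed days-difference summaries and
    tolerance-window confusion matrices with sensitivity, specificity,
    PPV, NPV, accuracy and F score, with exact binomial confidence
    intervals). A synthetic biphasic-cycle simulator reproduces the
    statistical structure of a side-by-side skin/vaginal sensor study
    population so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
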