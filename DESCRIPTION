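Package: gahrdesign
Title: Sample Size for Composite Time-to-Event Endpoints via the
    Geometric Average Hazard Ratio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design of two-arm randomized trials whose primary endpoint is a
    two-component composite time-to-event outcome (e.g. progression-free
    survival). The joint law of the latent component times is modelled with an
    Archimedean copula (Frank, Clayton or Gumbel) and Weibull margins, with
    scale parameters calibrated from anticipated event probabilities and
    cause-specific hazard ratios. From the calibrated model the package
    computes the time-varying all-cause hazard ratio HR*(t), its truncated
    geometric average gAHR(tau), and logrank-based required events, sample
    size and power, in which gAHR(tau) plays the role of the hazard ratio in
    Schoenfeld's formula. A Monte-Carlo engine simulates competing-risks trial
    data from the calibrated model and estimates the empirical power of the
    one-sided logrank test, both for single scenarios and for large scenario
    grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
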