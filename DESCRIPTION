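Package: itemprecision
Title: Precision-Based Sample Size Planning for Multi-Item Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans sample sizes for studies that measure many items (stimuli,
    questionnaire items, trials) by targeting accuracy in parameter
    estimation rather than power for a single hypothesis test. From pilot
    (or simulated) item-level data the package computes per-item standard
    errors, a decile-based precision cutoff that doubles as a sequential
    stopping rule, bootstrap percent-below-cutoff curves over a grid of
    candidate sample sizes, and corrected minimum and maximum sample sizes
    via an exponential-decay adjustment and a published nine-term regression
    correction. A simulation harness generates Likert, percent, and
    response-latency style populations with controllable item-variance
    heterogeneity, ceiling/floor skew, and bimodal mixtures, and evaluates
    the stability and bias of the recommendations across pilot sizes.
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
    withr
Config/testthat/edition: 3
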