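Package: ampain
Title: Attention Bias Malleability Analysis for Pain Reaction-Time Paradigms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, cleaning, scoring and inference for dot-probe
    attention-bias-malleability (AM) studies in pain research. Generates
    complete synthetic study datasets with known ground truth (five-block
    dot-probe paradigm with contingency training, random-interval-repetition
    tone detection under alternating pain episodes, questionnaire batteries),
    cleans trial-level reaction times (response window, unscaled
    median-absolute-deviation outlier rule, accuracy-based exclusion),
    computes per-participant attention-bias and malleability indices,
    scores the Pain Catastrophizing Scale, DASS-21, Graded Chronic Pain
    Scale and attention-to-pain items, and runs hierarchical regressions
    with R-squared change, F-change, standardized coefficients, Cohen's
    f-squared and Bonferroni control, plus index-trait correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
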