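Package: cytocea
Title: Cost-Effectiveness of Cervical Cytology Collection Devices
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analysis model of conventional Pap-smear screening for
    HIV-infected women, comparing the wooden elongated-tip (Aylesbury) spatula
    with the plastic Cervex-Brush ("broom") collection device. Implements both
    the guidelines (intended-practice) and typical-practice screening trees
    with recall/repeat dynamics, a Monte Carlo probabilistic sensitivity
    analysis over the model's parameter registry, programme-cost and
    cost-per-HSIL-detected economics with incremental (dominance) comparisons,
    and an individual-level microsimulation that doubles as a synthetic
    laboratory-record generator and brute-force validation oracle for the
    cohort-expectation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
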