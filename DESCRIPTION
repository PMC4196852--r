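Package: sddicost
Title: Decision-Tree Cost Model and Probabilistic Sensitivity Analysis for
    Selective Digital Dermoscopy Follow-Up in Melanoma Detection
Version: 1.0.0
Authors@R:
    person("Sam", "Verhulst", email = "sam.verhulst@example.org",
           role = c("aut", "cre"))
Description: Implements a decision-tree cost-minimization model comparing the
    "extra-costs" of melanoma detection (excision and pathology of benign
    lesions, and/or follow-up visits) under two strategies: optical dermoscopy
    alone versus optical dermoscopy with selective sequential digital
    dermoscopy imaging (SDDI). Provides the Belgian 2012 billing-pathway cost
    accounting, construction of parameter distributions from observed cohort
    statistics, a seeded Monte Carlo probabilistic sensitivity analysis with
    credibility intervals, a standardized-regression (tornado) variable
    importance analysis, a synthetic patient-cohort generator for validation,
    and CSV/JSON reporting with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
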