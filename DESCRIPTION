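Package: fastview
Title: Street-Audit Instrument Scoring, Sampling and Reliability Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A toolkit for virtual and on-site street walkability audits built
    around the FASTVIEW instrument: a machine-readable audit schema (nine
    walkability categories, each with up to three ordered-level factors), a
    good/fair/poor data-reduction rule, road-network link segmentation and
    seeded sampling (800 m buffer, 50-300 m links), and intra-rater,
    inter-rater and criterion reliability analyses reporting percent
    agreement with Cohen's and Fleiss' kappa and Landis-Koch interpretation
    bands. Includes a synthetic multi-rater audit simulator with a known
    confusion-model ground truth so every agreement statistic can be checked
    against its theoretical value.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
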