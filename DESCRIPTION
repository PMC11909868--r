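Package: ipfcea
Title: Cost-Effectiveness Analysis of Diagnostic Strategies for
    Idiopathic Pulmonary Fibrosis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model comparing four
    diagnostic strategies for idiopathic pulmonary fibrosis (IPF): a
    machine-learning image classifier, a bronchoscopic genomic classifier,
    universal surgical lung biopsy, and universal empiric antifibrotic
    treatment. Provides a validated parameter registry with probabilistic
    sensitivity analysis (PSA) distributions, analytic evaluation of the
    diagnostic decision tree, Monte Carlo PSA, incremental
    cost-effectiveness ratio (ICER) efficiency frontiers with strong and
    extended dominance, cost-effectiveness acceptability curves, net
    monetary benefit, one-way/tornado/threshold sensitivity analyses,
    scenario analyses, and a patient-level microsimulation that serves as
    a brute-force check on the cohort model. All user-facing functions
    take and return data frames so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
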