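Package: faersror
Title: Disproportionality Analysis of FAERS-Style Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for drug-drug interaction signal detection in spontaneous
    adverse-event reporting data in the FDA Adverse Event Reporting System
    (FAERS) quarterly ASCII dialect. Implements report ingestion, case-level
    deduplication (most recent report per case), exclusion of reports where
    therapy started after event onset, drug-name normalization against a
    synonym dictionary, exposure-group construction for a target drug and
    comparators, and case/non-case disproportionality statistics: the
    reporting odds ratio with Woolf (log-normal) confidence intervals and a
    Wald test on the log odds ratio, with a lower-CI-above-one plus minimum
    case-count signal rule. A synthetic FAERS-like report generator with
    known ground truth supports calibration and end-to-end testing without
    access to the real database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
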