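Package: faerssignal
Title: Disproportionality and Time-to-Onset Analysis for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection on
    FDA Adverse Event Reporting System (FAERS) shaped quarterly ASCII data.
    Reads and writes the five quarterly tables (DEMO, DRUG, REAC, THER,
    OUTC), deduplicates reports by the FDA-preferred case rule, restricts
    to primary-suspect drugs, identifies target-event cases by MedDRA
    preferred term, computes reporting odds ratios with Wald confidence
    intervals and the standard signal criterion, fits two-parameter
    Weibull distributions to time-to-onset samples by profile-likelihood
    maximum likelihood with failure-type classification, and tabulates
    demographic and outcome descriptives. A synthetic-data generator with
    recorded ground truth (planted odds ratios, Weibull onset laws,
    duplicate structure) makes every stage testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    fitdistrplus,
    optparse,
    withr
Config/testthat/edition: 3
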