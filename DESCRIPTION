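Package: pvmine
Title: Disproportionality Signal Mining for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacovigilance disproportionality analysis of
    spontaneous adverse-event report extracts: reading, validating and
    deduplicating report-level data; building 2x2 contingency tables per
    (drug, event) pair; reporting odds ratio (ROR) and proportional
    reporting ratio (PRR) statistics with lognormal confidence intervals
    and chi-squared tests; joint signal criteria and frequency-ranked
    signal tables; preferred-term to system-organ-class aggregation and
    SOC-level disproportionality; demographics summaries; a synthetic
    spontaneous-reporting-system simulator with planted drug-event
    associations of known strength; and forensic inversion of published
    summary rows back to contingency tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
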