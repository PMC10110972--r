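Package: scarsignal
Title: Disproportionality Analysis of Severe Cutaneous Adverse Reaction Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pharmacovigilance pipeline for severe cutaneous adverse
    reactions (SCARs) in spontaneous adverse-event report databases.
    Identifies SCAR-related reports through the 18 narrow-scope MedDRA
    preferred terms of the SCAR Standardized MedDRA Query, extracts and
    normalizes primary-suspect culprit drugs with ATC classification,
    computes reporting odds ratios with 95% confidence intervals at the
    SMQ level and each preferred-term level (19 signals per drug),
    screens positive signals, and produces descriptive summary tables.
    Includes a reader/writer for the openFDA drug-event JSON dialect, a
    flat-table dialect for fixtures, and a synthetic spontaneous-report
    generator with configurable drug-reaction odds multipliers so the
    whole pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
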