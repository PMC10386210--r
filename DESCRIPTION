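Package: srssignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end pipeline for pharmacovigilance signal detection in
    spontaneous reporting system (SRS) databases distributed as linked
    DEMO/DRUG/REAC tables keyed by a case identification number (the JADER
    dialect). Reads and cleans the raw tables (semicolon stacking,
    deduplication, key join, indicator-medication exclusion), computes
    Haldane-corrected reporting odds ratios with log-scale confidence
    intervals and two-sided Fisher exact tests for a drug panel against a
    MedDRA preferred-term event set, produces volcano-plot coordinates,
    compares demographics between event and non-event cases, and
    characterises signal structure via a filtered lnROR matrix, Ward
    hierarchical clustering, and covariance-matrix principal component
    analysis. A synthetic JADER-shaped database generator with known injected
    association strengths supports validation without access to the real
    database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
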