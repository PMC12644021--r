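Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for case/non-case disproportionality analysis of
    FAERS-style spontaneous adverse-event report databases, built around the
    tubulointerstitial nephritis (TIN) signal under statin exposure. Reads and
    writes FAERS quarterly ASCII file families (DEMO, DRUG, REAC, OUTC), joins
    them on PRIMARYID, deduplicates reports and retains the latest case
    version, classifies statin primary-suspect exposure from DRUGNAME/PROD_AI,
    and computes the reporting odds ratio (with Woolf intervals), proportional
    reporting ratio, empirical Bayes geometric mean under the two-component
    gamma-Poisson (MGPS) shrinker, and the information component, with
    four-threshold signal flagging per calendar year. A synthetic
    spontaneous-report generator with planted reporting-rate ratios makes
    every pipeline stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
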