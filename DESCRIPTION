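Package: almostsig
Title: Detection and Temporal Trend Analysis of Almost-Significant
    Phrasing in Clinical Trial Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how randomized controlled trial reports
    describe results that approach but do not reach statistical
    significance. Scans normalized full-text article records for a
    dictionary of "almost significant" phrases, extracts P values
    reported within a fixed character window after each phrase, estimates
    yearly and multi-year phrase prevalence with continuity-corrected
    Wilson confidence intervals, and scores per-phrase temporal trends
    with Jeffreys-Zellner-Siow Bayes factors comparing a linear-trend
    regression against an intercept-only model. Includes a seeded
    synthetic corpus generator with ground truth so the full pipeline can
    be exercised and calibrated without access to the original articles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    stringi,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
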