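Package: platewell
Title: Microplate Assay Management and Dose-Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A scriptable laboratory-information toolkit for microplate
    assays: a stepwise plate-design data model (plate types, reusable
    layouts with control/blank/substance markers, master plates with
    dilution series, barcoded plate instances), an Excel-like formula
    engine for per-well and per-plate calculations with outlier-aware
    group aggregates, import of plate-reader raw data matched by barcode,
    screening QC statistics (CV%, Z-scores), dose-response curve
    construction with IC50 estimation by log-linear interpolation or by
    a four-parameter Hill fit, an auditing document store with soft
    deletion, a synthetic-plate simulator for end-to-end validation, and
    a command-line workbench tying the workflow together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
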