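Package: sterolri
Title: Phytosterol Annotation for GC/EI-MS with Fatty Acid Pyrrolidide
    Retention Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for the determination of silylated phytosterols and
    pentacyclic triterpene alcohols in vegetable oils by GC/EI-MS. Computes
    temperature-programmed retention indices against a fatty acid pyrrolidide
    (FAP) homologue ladder, supports retention time locking via a five-point
    pressure calibration, derives trimethylsilyl molecular and diagnostic
    fragment ions for sterol classes, builds selected-ion-monitoring (SIM)
    time-window schedules under an ion budget, annotates peak tables with a
    rule engine and a 4-level assignment scheme, reports semi-quantitative
    TIC compositions, and generates synthetic chromatograms (four built-in
    vegetable-oil profiles, drift and locking models) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
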