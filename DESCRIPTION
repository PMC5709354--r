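Package: ntpkit
Title: Nearest-Template Prediction with Cancer Cell-Intrinsic Marker Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Platform-independent molecular subtyping of bulk expression
    profiles by nearest-template prediction (NTP) with gene-resampling
    confidence estimates and a false discovery rate based "not assigned"
    rule. Includes a three-filter procedure for deriving cancer
    cell-intrinsic subtype marker templates (differential expression
    candidates, cell-line robustness, tumor-versus-xenograft intrinsic
    filtering), gene-set diagnostics (hypergeometric enrichment, a
    fixed-correlation competitive gene-set test, single-sample enrichment
    scores), a synthetic multi-cohort data generator with planted subtype
    and stromal structure, and evaluation experiments (overall accuracy,
    template concordance, random-subset stability, cycle consistency).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    limma,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
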