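Package: polpause
Title: RNA Polymerase II Promoter-Proximal Pausing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying RNA polymerase II promoter-proximal
    pausing from ChIP-seq and nascent-RNA (4sU-seq) coverage tracks.
    Implements spike-in ("reference genome") library calibration,
    input-normalized enrichment tracks, the Pol II release ratio (PRR)
    statistic with stratified condition comparisons, DRB/4sU wave-front
    detection and elongation-rate estimation, scaled and TSS-centered
    metagene profiles, peak-to-gene target assignment with bound-set
    intersection and class-enrichment tests, and a deterministic
    synthetic-data generator that emulates the coverage structure these
    estimators consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
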