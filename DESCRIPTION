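Package: phosmiR
Title: Plant Small RNA Discovery and Phosphate-Starvation Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for genome-wide plant microRNA discovery
    from small RNA sequencing libraries and for characterising their
    phosphate-starvation responses. Covers adapter trimming and read
    accounting, exact-match genome mapping with origin categorisation,
    hairpin extraction with MFE/MFEI filtering under a seven-criterion
    miRNA definition, TPM-based induction/repression and tissue-specificity
    calls, degradome-supported cleavage-site target calling with
    target-mimic detection, and promoter cis-element scanning. Ships a
    synthetic-data generator with planted ground truth so every stage is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: ViennaRNA (RNAfold on PATH)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
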