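Package: codonreprog
Title: Codon-Biased Translation Reprogramming Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream statistics for codon-biased translational
    reprogramming studies: per-gene codon and amino-acid content with
    rank-based top-quartile enrichment testing against a transcriptome
    background, tRNA isodecoder aggregation to isoacceptor and
    alloisoacceptor levels with differential tests and codon/tRNA
    concordance overlays, ribosome-footprint metagene density and
    site-resolved codon occupancy shifts, codon-content-stratified
    fold-change comparisons, and the thresholded multi-omic derivation
    of a translational gene signature with single-sample enrichment
    (ssGSEA) scoring of expression cohorts. A synthetic-data generator
    with planted effects provides fully reproducible inputs for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
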