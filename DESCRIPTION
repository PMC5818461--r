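Package: crckit
Title: Discovery, Classification, Dating and Mapping of Centromeric LTR
    Retrotransposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural de novo discovery of LTR retrotransposons from genome
    assemblies, translated-search annotation of their coding domains,
    chromodomain/CR-motif typing, family definition from reverse-transcriptase
    phylogenies with bootstrap support, non-autonomous element classification
    (TRIM, LARD, TR-GAG), genome-wide copy census at coverage/identity
    thresholds, Kimura two-parameter insertion dating, repeat density tracks
    and satellite-array detection. Includes a synthetic-genome simulator that
    plants elements of known family, age and state of decay, so every stage
    of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    data.table,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
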