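Package: promforge
Title: Design and Quantification of Short Germline-Specific Promoters in C. elegans
Version: 0.9.0
Authors@R:
    person("Promforge", "Developers", email = "promforge@example.org",
           role = c("aut", "cre"))
Description: A workflow for designing compact germline-specific promoters for
    single-copy reporter transgenes in Caenorhabditis elegans. Ranks genes by
    relative germline expression from tissue-resolved TPM tables, extracts
    short intergenic promoter regions from genome annotation, makes sequences
    synthesis-ready by scrubbing long homopolymers and BsaI type-IIS
    recognition sites with minimal single-base substitutions, simulates BsaI
    Golden Gate digestion and ligation to assemble reporter constructs, and
    gates and summarizes COPAS large-particle flow-cytometry measurements of
    reporter expression. Ships a characterized panel of twenty promoter
    sequences as a plain-text fixture and synthetic-data generators with known
    ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
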