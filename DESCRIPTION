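Package: telotru
Title: Telomeric Repeat Unit Discovery and Long-Read Telomere Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discover short tandem telomeric repeat units (TRUs) at
    the termini of chromosome-scale assemblies, annotate TRU arrays in
    assemblies and long reads, and classify long reads as telomere-supporting
    (array flush with a read terminus), interstitial/subtelomeric, or
    chimeric, summarising per-arm telomere support. Includes a seeded
    simulator of telomere-bearing genomes and noisy long reads with truth
    labels, so every stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    tools,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
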