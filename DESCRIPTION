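Package: sgatools
Title: Streaming ChIP-Seq Analysis on the SGA Single-Position Format
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ChIP-seq and related single-position genomic data in
    the SGA (Simple Genome Annotation) format: parsing, validation, sorting,
    sort-merging and conversion to and from BED, BAM and GFF; tag centering
    and blacklist filtering; feature correlation (aggregation profiles,
    per-reference count matrices, reference scoring); sliding-window peak
    calling; dynamic-programming genome segmentation into enriched domains;
    Gaussian fitting of strand cross-correlation histograms for fragment
    length estimation and peak-parameter recommendation; and a seeded
    synthetic ChIP-seq read generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
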