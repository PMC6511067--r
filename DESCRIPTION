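Package: genofilter
Title: Chunked Genotype Store and Two-Group Variant Filtering Engine
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stores multi-sample genotype datasets imported from VCF, PLINK
    (PED/MAP) or HapMap files in a chunked on-disk layout that separates an
    indexed variant-level table from per-chunk genotype runs, and evaluates
    queries combining variant-level filters (type, allele count, sequence,
    position, functional annotation) with up to two per-group genotype-level
    filter blocks (genotype patterns, minor allele frequency, missing-data
    ratio, numeric-field thresholds) including case-control group
    discrimination. Query counts are cached per chunk so repeated counts are
    instant and finds can stop early. Includes density binning with cumulated
    numeric-field series, exporters for VCF, PLINK, HapMap and Flapjack
    (.fjzip), a deterministic synthetic-VCF generator with planted
    group-discriminating variants, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    parallel,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
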