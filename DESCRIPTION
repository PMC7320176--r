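Package: sbdrivers
Title: Driver-Gene Discovery from Sleeping Beauty Insertional Mutagenesis Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Sleeping Beauty (SB) transposon
    insertional-mutagenesis screens in mouse mammary tumours: processing of
    splinkerette junction reads into deduplicated, oriented insertion sites;
    Poisson common-insertion-site (CIS) statistics over gene bodies plus a
    3 kb upstream window with a two-strain recurrence filter;
    oncogene/tumour-suppressor classification from insertion orientation bias
    and positional clustering; exon-level activation-breakpoint detection from
    normalized exon counts; and a cross-species expression-binned
    subtype-incidence correlation screen with two-database consensus. A
    synthetic-data module generates genomes, screens, junction reads, exon
    profiles and patient cohorts with the statistical structure the analysis
    assumes, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
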