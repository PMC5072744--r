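Package: ltrsites
Title: Mapping and Quantifying Retroviral Integration Sites from
    LTR-Anchored and Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovers and quantifies retroviral (HIV-1-style) integration
    sites in a host genome from two evidence streams: LTR-anchored amplicon
    sequencing (modified TraDIS/splinkerette libraries) and whole-genome
    shotgun sequencing. Implements read-pair merging, splinkerette and
    LTR-anchor processing, a k-mer seed-and-extend mapper with mapping
    quality, the four-criterion junction authenticity filter, PCR
    deduplication, 250-bp single-linkage clustering, integrase-catalyzed
    versus unresolved junction classification, chimeric-read detection in
    WGS with partial/independent/virus-only pair categories, a per-nucleus
    integration-burden estimator with exact Clopper-Pearson confidence
    intervals, genomic region (exon/intron/intergenic) annotation with a
    one-tailed binomial bias test, and a synthetic-data module that
    generates host genomes, planted proviruses and read sets with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
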