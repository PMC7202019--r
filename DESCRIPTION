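Package: rebelkit
Title: Detection and Annotation of Ta-Subfamily LINE-1 Insertion Junctions
    from Targeted Amplicon Sequencing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls putative human-specific LINE-1 (L1Hs, Ta subfamily)
    retrotransposon insertion junctions from targeted-amplicon sequencing
    alignments.  Provides strand-aware clustering of junction-anchored
    reads into peaks, poly(T) k-mer trimming of unaligned reads,
    annotation of peaks against reference and known non-reference
    insertion catalogs in BED format, empirical quality filters
    (index-hop remediation across multiplexed pools, a mapping-quality
    cutoff derived from reference insertions, and an average
    reads-per-carrier cutoff), validation-rate statistics over read-depth
    bins, and a synthetic-data generator that plants insertions in toy
    genomes so every stage can be exercised without restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    jsonlite
Config/testthat/edition: 3
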