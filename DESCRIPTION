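Package: l1peak
Title: Detection and Analysis of LINE-1 Insertions from 3'-Anchored
    Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of an L1-seq style analysis of
    LINE-1 (L1) retrotransposon insertions in pooled genomes from
    3'-anchored hemi-specific amplicon sequencing.  Provides a synthetic
    data generator (toy genomes, planted insertions with zygosity and
    mosaic fraction, pooled amplicon reads, droplet counts), read
    trimming and quality filtering, a seed-and-extend toy aligner,
    strand-aware peak calling with known-reference/known-non-reference/
    novel classification, per-pool and per-population comparison with
    Fisher's exact test, hypergeometric and binomial gene-set
    over-representation with Bonferroni correction, and droplet digital
    PCR Poisson quantification with allele-ratio and expression models.
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
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
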