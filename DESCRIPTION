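Package: sharest
Title: Leaf Transcriptome Screening, Orthology and SNP Mining for Wild Wheat EST Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing normalised-cDNA long-read transcriptome surveys of
    wild wheat relatives such as Aegilops sharonensis. Implements the read-screening
    cascade (length filter plus repeat, organelle and human contamination screens),
    assembly quality statistics (N50, contig-length versus read-count correlation,
    self-alignment redundancy), best-reciprocal-hit orthology with core-ortholog set
    algebra and genetic-map placement, greedy identity clustering to a non-redundant
    representative set, NB-LRR resistance-gene mining by a two-stage NB-ARC/LRR domain
    cascade and a lexical annotation search, Bayesian two-accession SNP calling from
    read pileups, and allelic-ratio heterozygosity estimation. A self-contained seeded
    Smith-Waterman similarity engine and a synthetic-data generator with planted ground
    truth make the whole pipeline runnable and testable without external search tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
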