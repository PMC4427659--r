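Package: sporescan
Title: Profile-Based Detection of Endospore-Formation Marker Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects sporulation marker genes (spo0A, gpr) in genomes,
    metagenome contigs and amplicon reads using Gribskov-style
    position-specific scoring profiles. Provides best-reciprocal-hit
    ortholog delineation, profile construction from multiple alignments,
    local profile-sequence alignment by dynamic programming, shuffled-null
    score-cutoff calibration, genome validation, six-frame metagenome
    contig screening, amplicon quality control, and a seeded synthetic-data
    generator so every stage can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
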