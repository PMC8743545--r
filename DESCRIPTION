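Package: replitopo
Title: Replicon Topology, Copy Number and Cas9 Spacer Analysis for
    Multi-Replicon Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of shotgun short-read data from bacteria with
    multi-replicon genomes composed of linear chromosomes and linear
    plasmids, such as Streptomyces. Detects whole-replicon loss and
    terminal chromosomal deletions from coverage profiles, calls
    chromosome circularization from split-read and split-contig junction
    evidence, estimates per-replicon copy numbers relative to the
    chromosome, locates terminal inverted repeats (TIRs) of linear
    replicons, and designs Cas9 NGG protospacers screened genome-wide for
    off-targets. Includes a deterministic synthetic-genome and paired-end
    read simulator so every stage of the pipeline is testable without
    external sequencing data, and a built-in exact k-mer seed-and-extend
    mapper capable of reporting split alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
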