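#!/usr/bin/env Rscript

# OPTIONAL real-data integration checks. These require network access and
# several GB of downloads, so they are not part of the default test suite.
#
# What they verify, given the public accessions:
#   1. TIR of the 149,702 bp linear plasmid (assembly GCA_015708605.1,
#      sequences CP045847-CP045850): find_tir with the default 2 kb window
#      should report a 348 bp repeat at 99 % identity (4 differences),
#      running over the first 413 bp at the left end with the right copy
#      missing its first 65 bp.
#   2. Terminal motif of the 11,696 bp plasmid (accession X54107):
#      terminal_motif(k = 7) should return the pair CCCGCGG / CCCGCGG.
#   3. Copy-number census of the deposited type-strain isolates
#      (BioProject PRJNA587782): the 444 kb plasmid should read out near
#      0.2 copies per chromosome in the ATCC 27064 deposit and near 1 in
#      NCIMB 14335.
#   4. Terminal-boundary detection on the cured clones (BioProject
#      PRJNA587886): the first circularized clone shows a left coverage
#      cut-off near position 98,990-98,994.
#
# Sketch (requires the NCBI datasets/sra-tools CLIs on PATH):
#
#   datasets download genome accession GCA_015708605.1
#   # unzip, then per replicon:
#   Rscript -e '
#     library(replitopo)
#     g <- read_fasta("GCA_015708605.1.fasta")
#     for (r in g$replicons) {
#       t <- find_tir(r, window = 2000)
#       if (!is.null(t)) print(t)
#     }'
#
#   prefetch SRRXXXXXXX && fasterq-dump SRRXXXXXXX   # per isolate
#   bwa index ref.fasta && bwa mem ref.fasta R1.fq R2.fq > aln.sam
#   Rscript -e '
#     library(replitopo)
#     g <- read_fasta("ref.fasta", chromosome_name = "CP045847.1")
#     segs <- read_sam("aln.sam", g)
#     print(copy_number(coverage_profiles(segs, g), g$chromosome_name))'

message("This script documents network-requiring integration checks; ",
        "see the comments for the recipe.")
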