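---
title: "Calling replicon loss, terminal deletions and chromosome circularization from short reads"
author: "replitopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling replicon loss, terminal deletions and chromosome circularization from short reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replitopo)
```

## The problem

*Streptomyces* and related actinomycetes keep their genomes on several
independently replicating molecules: one large **linear** chromosome plus
linear (and sometimes circular) plasmids spanning four orders of magnitude
in size, from ~10 kb plasmids to megaplasmids of 1-2 Mb. Linear replicons
end in **terminal inverted repeats (TIRs)** capped by covalently bound
terminal proteins, and the machinery that replicates those ends (the
*tap*-*tpg* gene pair) may reside on a plasmid rather than the chromosome.
Curing such a plasmid — for instance with a Cas9 double-strand break in its
partitioning gene *parB* — can therefore destabilize the chromosome ends
themselves: derivative strains lose large terminal chromosomal segments,
and the chromosome may fuse its two ends into a circle.

Given shotgun paired-end reads from a derivative strain and the parental
multi-replicon reference, this package answers four questions:

1. **Which replicons are still there, and at what copy number?**
   (coverage breadth and depth ratios)
2. **Where do retained chromosome ends stop?** (terminal coverage
   boundaries)
3. **Did the chromosome circularize?** (split-read/contig junction
   evidence joining the two retained ends)
4. Supporting analyses: **TIR detection** on linear replicons and
   **off-target-free Cas9 spacer design** for constructing such strains in
   the first place.

A deterministic synthetic-genome and read simulator provides ground truth
for every stage, so the full pipeline is testable without any external
sequencing data.

## Models and procedures

### Mapping

The built-in mapper is an exact k-mer seed (default $k = 31$) and
ungapped-extension aligner. Each reference position is indexed; query
k-mers (probed at a stride of 10, which still guarantees a seed in any
exact stretch of $\ge k + 9 = 40$ bp, below the 50 bp minimum anchor) vote
for (replicon, strand, diagonal) candidates, and each candidate diagonal
is scanned once for its maximum-scoring ungapped block (+1 match, −3
mismatch). This design has two properties the downstream logic relies on:

* a chimeric query — a read or contig spanning a fusion junction — falls
  apart into one maximal block per locus, giving the split
  (primary + supplementary) segments junction calling consumes;
* reads lying entirely inside a TIR match both ends of their replicon
  equally well; equal-scoring placements are resolved to the lowest
  (replicon, position) for determinism, flagged `ambiguous`, and excluded
  from junction evidence.

Substitution-rich data is handled (mismatch rate ≤ 0.05 per segment by
default), but there is deliberately no gapped extension: positions and
depth, not indel fidelity, drive every call. Indel-rich real data should
be aligned with a production mapper and imported as SAM — the pipeline
accepts either route and the test suite verifies both give identical
downstream calls.

### Replicon census

For each replicon we compute the trimmed mean depth
$\bar d = \mathrm{mean}(d_i),\ i \in [t+1, n-t]$ with $t$ one read length,
the **copy-number ratio** $\bar d_{\text{replicon}} / \bar
d_{\text{chromosome}}$ (the standard read-depth proxy for plasmid copies
per chromosome), and the **breadth** — the fraction of positions covered
at depth ≥ 1. Presence calls operationalize the qualitative dichotomy
between "complete coverage" and "essentially none": breadth ≥ 0.95 is
`present`, ≤ 0.05 is `absent`, anything between is `partial`.

Two deliberate robustness choices:

* **Trimmed, not plain, means.** Linear replicons mechanically lose
  coverage over roughly a read length at each terminus (fragments must lie
  wholly inside the molecule), and short-read libraries can show localized
  artifact peaks; both would bias plain-mean ratios.
* **Breadth over the trimmed interior.** The same terminal dip — plus TIR
  placement ambiguity — costs a 5 kb plasmid ~6 % of its positions, enough
  to misclassify a fully retained small plasmid under the 0.95 threshold.
  Breadth is therefore computed over the same trimmed interior as the
  depth mean. A chromosome that lost ~20 % of its length to terminal
  deletions will read out `partial` here, which is accurate at the census
  level; the topology caller, not the census, is the authority on terminal
  deletions.

### Terminal boundaries

The left boundary is the smallest position $p$ whose following
`min_run` = 100 bp are all covered at depth ≥ 2; the right boundary is
symmetric. Keying on *sustained runs* rather than the first covered base
makes the boundary robust to stray coverage peaks beyond the true
boundary (chimeric/PCR artifacts, possible unresolved rearrangements) —
those are surfaced as warnings, never as calls. A boundary within
`terminal_dip` = 300 bp (twice the default read length) of the terminus
snaps to the terminus, absorbing the mechanical dip of intact linear
ends.

### Junction evidence and the circularization call

A circularized chromosome joins its last retained right-end position $R$
to its first retained left-end position $L$. A query spanning the fusion
contributes evidence iff it has two same-strand segments, one ending at
some $R$ in the right terminal window, one starting at some $L$ in the
left window, with consecutive query intervals (right anchor before left
anchor after strand normalization; |gap| ≤ 10 bp). Microhomology at the
fusion point makes the breakpoint intrinsically ambiguous by the homology
length — the two anchors then overlap on the query — and we canonicalize
by assigning the shared bases to the left anchor, so all reads over one
junction report identical $(L, R)$.

`call_topology` then applies the decision rule:

* junction records are clustered by $(L, R)$ agreement within
  `tolerance` = 300 bp; a cluster is *sufficient* with ≥ 2 concordant
  queries **or** a single query with both anchors ≥ 500 bp (one long
  assembled contig is as decisive as multiple reads);
* a sufficient cluster whose consensus agrees with the coverage
  boundaries within tolerance yields `circularized`, with the
  junction-derived $(L, R)$ overriding the coverage cut-offs — junctions
  are base-precise, coverage boundaries are read-length-limited. Larger
  disagreements are flagged, and the call falls back to coverage;
* boundaries showing deletions without sufficient junction evidence yield
  `terminal_deletion_only` — deliberately *not* a claim of linearity,
  since absence of junction reads does not rule circularization out; the
  three-way status preserves that uncertainty;
* two mutually exclusive sufficient clusters are an error, not a call.

Derived quantities: deletions $L-1$ and $n-R$ bp, reported in kb rounded
half away from zero, and the genome-loss percentage
$100 (\sum \text{lost replicons} + (L-1) + (n-R)) / \text{parental
total}$.

### TIR finder

The first `window` = 2,000 bases are aligned against the reverse
complement of the last 2,000 by the best-scoring **ungapped** local block
(+1/−2, every diagonal scanned by maximum subarray). Ungapped alignment
keeps "number of differences" well defined; identity is rounded to
integer percent (344 matches in a 348 bp block reads out as 99 %). When
one copy is truncated at its terminus the report carries the missing
extent (`right_truncation`), e.g. a right copy missing its first 65 bp of
a 413 bp idealized repeat aligns as a 348 bp block starting at left-end
position 66.

### Spacer design

All 20-mers 5′ of an NGG on either strand of the target region are
enumerated, then screened genome-wide: an off-target site is any
NGG-adjacent 20-mer (both strands, all replicons) within Hamming distance
`max_mismatches` = 2 of the spacer, excluding the on-target site.
A Hamming-distance contract is explicit and oracle-checkable; an optional
stricter seed rule (no mismatches tolerated in the PAM-proximal 12 bases)
reflects common Cas9 practice and is off by default. Unique candidates
are ranked by fewest near-miss sites at distance 3 (margin of safety),
then position. An empty result is a valid, explicitly reported outcome.

## The synthetic-data generator

`generate_replicon` draws i.i.d. bases at a target GC (default 0.70, the
actinomycete regime, which also makes NGG PAMs frequent) and plants exact
TIRs by reverse-complementing the prefix onto the suffix.
`derive_strain` applies whole-replicon drops and circularization events:
on a length-$n$ replicon with deletions $(d_l, d_r)$ the derived circle
has length $n - d_l - d_r$, starts at parental position $d_l + 1$ and
ends at $n - d_r$, the origin being the fusion junction.
`simulate_reads` draws Poisson pair counts with expectation
$\text{depth} \times n / (2 \times \text{read length})$, Normal insert
sizes truncated at the read length, and uniform substitution errors;
linear replicons sample fragments wholly inside the molecule (which
mechanically depresses terminal depth, the signature real data shows at
linear ends), circular replicons sample across the origin. Copy number is
simulated by scaling per-replicon depth.

The shipped desk-scale fixture preserves the size hierarchy of the real
system: a 500 kb chromosome, a 50 kb megaplasmid at 1 copy per
chromosome, a 5 kb plasmid at 2 copies, 400 bp TIRs, 50× depth, 150 bp
reads; the matching cured-strain spec drops the megaplasmid and
circularizes the chromosome with deletions of 7,334 and 8,588 bp —
proportional to ~99 kb and ~116 kb on a 6.75 Mb chromosome.

What the generator does **not** model — and hence what passing tests do
not show about real data: PCR-library coverage bias (real depth profiles
show amplification peaks; no quantitative model for them is published, so
we deliberately do not invent one), indels and structural sequencing
artifacts, base-quality information, chimeric library molecules, and
subpopulation mixtures (a culture in which only some cells retain a
plasmid produces fractional apparent copy number; the census reports the
ratio without deconvolving it).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `k` | 31 | bp | seed length; effectively unique in high-GC genomes at these scales |
| `min_anchor` | 50 | bp | shorter anchors are too noisy to serve as junction evidence |
| `max_mismatch_rate` | 0.05 | /bp | tolerates substitution errors without admitting spurious blocks |
| `end_trim` | 150 | bp | one read length; spans the mechanical terminal dip |
| `present_breadth_min` / `absent_breadth_max` | 0.95 / 0.05 | — | operationalize "complete coverage" vs "lacking" |
| `boundary_min_depth`, `boundary_min_run` | 2, 100 | ×, bp | sustained-run boundary criterion |
| `terminal_dip` | 300 | bp | snap-to-terminus tolerance, 2× read length |
| `terminal_window` | 200,000 | bp | anchor search window; covers deletions up to ~120 kb with slack |
| `tolerance` | 300 | bp | junction-vs-boundary agreement, 2× read length |
| `min_evidence` / `long_anchor` | 2 / 500 | queries / bp | reads corroborate each other; one long contig stands alone |
| `tir_window` | 2,000 | bp | terminal probe window |
| `max_mismatches` | 2 | — | off-target Hamming radius over the 20-mer |

## Numerical and degenerate-case choices

* Coordinates are 1-based inclusive at **every** interface; any half-open
  arithmetic is internal.
* Ambiguity codes (N) are rejected at ingest: the k-mer index and Hamming
  screens assume a 4-letter alphabet. Mask or trim real data first.
* Mapper ties are broken to the lowest (replicon, position, strand) and
  flagged; determinism everywhere is byte-level (same inputs, parameters
  and seed give byte-identical reports, verified in the suite).
* kb rounding is half away from zero, which reproduces printed kb figures
  from printed coordinates exactly.
* An all-zero profile raises "effectively absent" rather than returning a
  fake boundary; a zero-depth chromosome is an error for the census since
  nothing can be normalized.
* Junction `R` is canonicalized under microhomology (shared bases to the
  left anchor); the representation ambiguity this resolves is inherent to
  fusion breakpoints, not an artifact.
* `simulate_reads` restores the RNG state it uses, so simulation never
  perturbs a caller's random stream.

## Problem sizes used by the test suite

Unit tests run on 3-30 kb replicons where brute-force oracles (cubic
best-block search, exhaustive Hamming scans, substring searches) are
exact and fast. The end-to-end recovery checks run the shipped full-scale
fixture (555 kb of genome at 50×, ~170k reads per run) across 20
simulation seeds, and copy-number recovery at 30× with plasmids at 0.2,
1 and 2 copies per chromosome. These sizes were chosen so the whole suite
exercises every code path at realistic depth in a few minutes on one
core.

## Known limitations

* The mapper is ungapped; indel-rich or structurally messy real data
  must come in as external SAM.
* The census cannot distinguish a low-copy plasmid from a mixed
  population partially carrying it.
* `terminal_deletion_only` is a statement about evidence, not topology;
  deciding those cases needs long reads or assembled contigs spanning the
  putative junction.
* Rearrangements other than terminal deletion + circularization are
  surfaced only as coverage warnings.
* The TIR finder reports the single best block per replicon; nested or
  highly diverged repeat structures are out of scope.
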