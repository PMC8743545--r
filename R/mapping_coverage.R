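#' Map queries onto a genome with the built-in seed-and-extend mapper
#'
#' A minimal exact-k-mer seed and ungapped-extend mapper, sufficient for
#' position- and depth-driven analyses of short reads and assembled contigs.
#' Chimeric queries — e.g. reads or contigs spanning the fusion junction of
#' a circularized chromosome — split into one segment per locus, with the
#' best-scoring segment as `primary` and the rest as `supplementary`;
#' this split evidence is what junction calling consumes. Equal-scoring
#' alternative placements of the same query stretch (e.g. reads lying
#' entirely within a terminal inverted repeat, which occurs at both ends of
#' a linear replicon) keep the lowest-(replicon, position) placement and are
#' flagged `ambiguous`; junction evidence excludes them. Indel-rich real
#' data should instead be aligned with a production mapper and imported via
#' [read_sam()] — the two routes are interchangeable downstream.
#'
#' Circular replicons are mapped through a doubled-sequence index with
#' positions reported modulo the replicon length; origin-crossing
#' alignments are split at the origin.
#'
#' @param genome A [genome()].
#' @param queries Character vector of query sequences, a reads data frame
#'   from [simulate_reads()]/[read_fastq()], or a named character vector.
#' @param k Seed k-mer length (4-31).
#' @param min_anchor Minimum reported segment length in bp; anchors shorter
#'   than this carry too little placement information to serve as junction
#'   evidence.
#' @param max_mismatch_rate Maximum mismatches per aligned base.
#' @param seed_stride Query k-mer sampling stride; the reference is indexed
#'   at every position, so any exact stretch of at least
#'   `k + seed_stride - 1` bp is still guaranteed a seed (40 bp at the
#'   defaults, below `min_anchor`).
#' @return Data frame of alignment segments with columns `query_id`,
#'   `qstart`, `qend`, `qlen` (1-based inclusive on the query as given),
#'   `replicon`, `rstart`, `rend` (1-based inclusive), `strand` (`+`/`-`),
#'   `edit_distance`, `role` (`primary`/`supplementary`), `ambiguous`.
#' @export
map_reads <- function(genome, queries, k = 31, min_anchor = 50,
                      max_mismatch_rate = 0.05, seed_stride = 10) {
  if (is.data.frame(queries)) {
    ids <- queries$id
    seqs <- queries$sequence
  } else {
    seqs <- as.character(queries)
    ids <- names(queries)
    if (is.null(ids)) ids <- sprintf("query_%d", seq_along(seqs))
  }
  if (!length(seqs)) return(.empty_segments())
  if (any(nchar(seqs) < k)) stop("k (", k, ") larger than shortest query")
  refs <- vapply(genome$replicons, `[[`, character(1), "sequence")
  circ <- vapply(genome$replicons, `[[`, character(1), "topology") == "circular"
  res <- cpp_map_queries(unname(refs), unname(circ), seqs,
                         as.integer(k), as.integer(min_anchor),
                         max_mismatch_rate, seed_stride = as.integer(seed_stride))
  data.frame(
    query_id = ids[res$qidx],
    qstart = res$qstart, qend = res$qend, qlen = res$qlen,
    replicon = names(genome$replicons)[res$ref],
    rstart = res$rstart, rend = res$rend,
    strand = c("+", "-")[res$strand + 1L],
    edit_distance = res$mism,
    role = c("primary", "supplementary")[res$role],
    ambiguous = res$ambiguous == 1L
  )
}

#' @rdname map_reads
#' @param query A single query sequence.
#' @export
map_query <- function(query, genome, k = 31, min_anchor = 50,
                      max_mismatch_rate = 0.05) {
  map_reads(genome, c(query_1 = as.character(query)), k = k,
            min_anchor = min_anchor, max_mismatch_rate = max_mismatch_rate)
}

#' Per-base coverage profile of one replicon
#'
#' `depth[i]` counts the alignment segments whose reference interval
#' contains position `i`; consequently `sum(depth)` equals the total number
#' of aligned reference bases contributed by the segments.
#'
#' @param segments Alignment-segment data frame (all rows must reference
#'   `replicon`; rows for other replicons are an error — subset first).
#' @param replicon A [replicon()].
#' @return Object of class `coverage_profile`: list with `replicon` (name),
#'   `depth` (integer vector of length `n`), `n`.
#' @export
compute_coverage <- function(segments, replicon) {
  n <- replicon$length
  segs <- segments[segments$replicon == replicon$name, , drop = FALSE]
  if (nrow(segs) != nrow(segments)) {
    stop("segments reference replicons other than '", replicon$name, "'")
  }
  depth <- integer(n)
  if (nrow(segs)) {
    if (any(segs$rstart < 1L | segs$rend > n)) {
      stop("segment out of bounds for replicon '", replicon$name, "'")
    }
    delta <- integer(n + 1L)
    starts <- tabulate(segs$rstart, nbins = n)
    ends <- tabulate(segs$rend + 1L, nbins = n + 1L)
    depth <- cumsum(starts - ends[seq_len(n)])
  }
  structure(list(replicon = replicon$name, depth = as.integer(depth), n = n),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s: n=%s, mean depth %.1f\n", x$replicon,
              format(x$n, big.mark = ","), mean(x$depth)))
  invisible(x)
}

#' Trimmed mean depth of a coverage profile
#'
#' Arithmetic mean of depth over `[end_trim + 1, n - end_trim]`. Trimming
#' both ends makes the summary robust to the depressed coverage at
#' linear-replicon termini and to localized artifact peaks, both of which
#' would otherwise bias copy-number ratios.
#'
#' @param profile A [compute_coverage()] profile.
#' @param end_trim Bases ignored at each end (must satisfy
#'   `2 * end_trim < n`).
#' @return Mean fold-depth.
#' @export
trimmed_mean_depth <- function(profile, end_trim = 0) {
  if (2 * end_trim >= profile$n) {
    stop("end_trim too large for replicon of length ", profile$n)
  }
  mean(profile$depth[(end_trim + 1L):(profile$n - end_trim)])
}

#' Coverage profiles for every replicon of a genome
#'
#' Convenience wrapper splitting a segment table by replicon.
#'
#' @param segments Alignment-segment data frame.
#' @param genome A [genome()].
#' @return Named list of `coverage_profile` objects, one per replicon.
#' @export
coverage_profiles <- function(segments, genome) {
  lapply(genome$replicons, function(r) {
    compute_coverage(segments[segments$replicon == r$name, , drop = FALSE], r)
  })
}
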