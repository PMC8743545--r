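#' Per-replicon copy number and presence calls from coverage
#'
#' Computes, for every replicon, the trimmed mean depth, the depth ratio
#' relative to the chromosome (the standard read-depth proxy for plasmid
#' copies per chromosome), and the breadth of coverage (fraction of
#' positions at depth >= `min_depth`). Breadth near 1 with depth comparable
#' to the chromosome indicates a retained replicon; breadth near 0
#' indicates a cured/lost replicon.
#'
#' @param profiles Named list of coverage profiles (see
#'   [coverage_profiles()]), which must include the chromosome.
#' @param chromosome_name Replicon used as the normalization reference.
#' @param end_trim Bases ignored at each replicon end for both the depth
#'   mean and the breadth (default one read length, tolerating the
#'   mechanical terminal coverage dips of linear replicons).
#' @param min_depth Minimum depth for a position to count as covered.
#' @param present_breadth_min,absent_breadth_max Breadth thresholds handed
#'   to [call_presence()].
#' @return Data frame with columns `replicon`, `mean_depth`,
#'   `ratio_vs_chromosome`, `breadth`, `status`.
#' @export
copy_number <- function(profiles, chromosome_name, end_trim = 150,
                        min_depth = 1, present_breadth_min = 0.95,
                        absent_breadth_max = 0.05) {
  if (!chromosome_name %in% names(profiles)) {
    stop("no coverage profile for chromosome '", chromosome_name, "'")
  }
  trim_for <- function(p) min(end_trim, floor((p$n - 1) / 2))
  chrom <- profiles[[chromosome_name]]
  chrom_depth <- trimmed_mean_depth(chrom, trim_for(chrom))
  if (chrom_depth <= 0) stop("chromosome has zero depth; cannot normalize")
  rows <- lapply(profiles, function(p) {
    tr <- trim_for(p)
    md <- trimmed_mean_depth(p, tr)
    # breadth over the trimmed interior: the mechanical coverage dip at
    # linear-replicon termini (and TIR placement ambiguity there) would
    # otherwise misclassify small retained replicons as partial
    br <- mean(p$depth[(tr + 1L):(p$n - tr)] >= min_depth)
    data.frame(
      replicon = p$replicon,
      mean_depth = md,
      ratio_vs_chromosome = md / chrom_depth,
      breadth = br,
      status = call_presence(br, present_breadth_min, absent_breadth_max)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Presence/absence call from breadth of coverage
#'
#' Operationalizes the qualitative dichotomy between "complete coverage"
#' (replicon retained) and essentially no coverage (replicon lost) with an
#' explicit `partial` middle ground for truncated or contaminating signal.
#'
#' @param breadth Fraction of positions covered at/above the minimum depth.
#' @param present_breadth_min Breadth at or above which a replicon is
#'   `present`.
#' @param absent_breadth_max Breadth at or below which it is `absent`.
#' @return `"present"`, `"absent"` or `"partial"`.
#' @export
call_presence <- function(breadth, present_breadth_min = 0.95,
                          absent_breadth_max = 0.05) {
  stopifnot(present_breadth_min > 0, present_breadth_min < 1,
            absent_breadth_max > 0, absent_breadth_max < 1)
  if (absent_breadth_max >= present_breadth_min) {
    stop("absent_breadth_max must be below present_breadth_min")
  }
  if (breadth >= present_breadth_min) "present"
  else if (breadth <= absent_breadth_max) "absent"
  else "partial"
}
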