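#' Detect the terminal boundary of retained sequence from coverage
#'
#' In a derivative strain with a terminal chromosomal deletion, aligned
#' reads show a sharp cut-off at the first retained position. The boundary
#' is the outermost position opening a *sustained* run of coverage: the
#' left boundary is the smallest position `p` with `depth >= min_depth`
#' over all of `[p, p + min_run - 1]`; the right boundary is symmetric.
#' Keying on sustained runs (not the first nonzero base) tolerates stray
#' coverage peaks beyond the true boundary from chimeric or PCR artifacts.
#'
#' Intact linear ends show a mechanical coverage dip over roughly a read
#' length (fragments must lie wholly inside the molecule) and, within TIRs,
#' ambiguous placements; a boundary found within `terminal_dip` of the
#' terminus is therefore snapped to the terminus itself.
#'
#' @param profile A coverage profile.
#' @param end `"left"` or `"right"`.
#' @param min_depth Minimum depth defining "covered".
#' @param min_run Minimum sustained run length in bp.
#' @param terminal_dip Dip tolerance in bp (default twice the default read
#'   length).
#' @return List of class `terminal_boundary`: `replicon`, `end`, `position`
#'   (first retained position for `left`, last retained for `right`),
#'   `support_depth` (mean depth over the qualifying run).
#' @export
detect_boundary <- function(profile, end = c("left", "right"), min_depth = 2,
                            min_run = 100, terminal_dip = 300) {
  end <- match.arg(end)
  n <- profile$n
  if (min_run > n) stop("min_run exceeds replicon length")
  covered <- profile$depth >= min_depth
  # positions opening a covered run of length min_run
  run_ok <- diff(c(0L, cumsum(covered)), lag = min_run) == min_run
  # run_ok[p] refers to window [p, p + min_run - 1]
  idx <- which(run_ok)
  if (!length(idx)) {
    stop("no sustained coverage run on '", profile$replicon,
         "': replicon effectively absent")
  }
  if (end == "left") {
    p <- idx[1]
    pos <- if (p <= terminal_dip) 1L else p
    support <- mean(profile$depth[p:(p + min_run - 1L)])
  } else {
    p <- idx[length(idx)] + min_run - 1L  # last position of last run
    pos <- if (n - p <= terminal_dip) n else p
    support <- mean(profile$depth[(p - min_run + 1L):p])
  }
  structure(list(replicon = profile$replicon, end = end, position = pos,
                 support_depth = support),
            class = "terminal_boundary")
}

#' Collect junction-spanning evidence for circularization
#'
#' A circularized chromosome joins its last retained right-end position `R`
#' to its first retained left-end position `L`. A read or contig spanning
#' the fusion maps as a split alignment: one segment anchored at the right
#' end (ending at `R`), one at the left end (starting at `L`), both on the
#' same strand, with consecutive query intervals (right anchor before left
#' anchor along the molecule, after strand normalization). Each such query
#' contributes one evidence record.
#'
#' Ambiguous-placement queries are excluded. `junction_gap` is the signed
#' number of query bases between the two anchors (negative = overlap); it
#' must not exceed `max_junction_gap` in magnitude. Anchor overlap arises
#' from microhomology at the fusion point, which makes the breakpoint
#' intrinsically ambiguous by the homology length; the reported `R` is
#' canonicalized by assigning the shared bases to the left anchor.
#'
#' @param segments Alignment-segment data frame (one replicon).
#' @param replicon The [replicon()] the segments refer to.
#' @param min_anchor Minimum anchor length per side (bp).
#' @param max_junction_gap Maximum |gap| between anchor query intervals.
#' @param terminal_window Only anchors ending within `terminal_window` of
#'   the right end / starting within it at the left end qualify; generous
#'   by default so large terminal deletions still fall inside.
#' @return Data frame with columns `query_id`, `R`, `L`,
#'   `right_anchor_len`, `left_anchor_len`, `junction_gap`.
#' @export
find_junctions <- function(segments, replicon, min_anchor = 50,
                           max_junction_gap = 10, terminal_window = 200000) {
  n <- replicon$length
  segs <- segments[segments$replicon == replicon$name & !segments$ambiguous, ,
                   drop = FALSE]
  out <- list()
  if (nrow(segs)) {
    split_ids <- names(which(table(segs$query_id) >= 2L))
    for (qid in split_ids) {
      s <- segs[segs$query_id == qid, , drop = FALSE]
      # normalize query intervals to molecule orientation: '-' segments are
      # flipped so intervals of a chimeric molecule read left-to-right
      qs <- ifelse(s$strand == "-", s$qlen - s$qend + 1L, s$qstart)
      qe <- ifelse(s$strand == "-", s$qlen - s$qstart + 1L, s$qend)
      len <- qe - qs + 1L
      right_ok <- s$rend > n - terminal_window & len >= min_anchor
      left_ok <- s$rstart <= terminal_window & len >= min_anchor
      for (i in which(right_ok)) {
        for (j in which(left_ok)) {
          if (i == j || s$strand[i] != s$strand[j]) next
          if (s$rstart[j] >= s$rend[i]) next       # need L < R
          gap <- qs[j] - qe[i] - 1L                # right anchor, then left
          if (gap < -max_junction_gap || gap > max_junction_gap) next
          # microhomology at the fusion makes the breakpoint ambiguous: the
          # anchors overlap on the query (gap < 0) and R overshoots by the
          # homology length; canonicalize by assigning the shared bases to
          # the left anchor, i.e. trim the right anchor back
          out[[length(out) + 1L]] <- data.frame(
            query_id = qid, R = s$rend[i] + min(0L, gap), L = s$rstart[j],
            right_anchor_len = len[i], left_anchor_len = len[j],
            junction_gap = gap
          )
        }
      }
    }
  }
  res <- do.call(rbind, c(out, list(data.frame(
    query_id = character(), R = integer(), L = integer(),
    right_anchor_len = integer(), left_anchor_len = integer(),
    junction_gap = integer()))))
  rownames(res) <- NULL
  res
}

#' Construct a circularization call
#'
#' Usually produced by [call_topology()]; the constructor is exported so
#' calls can also be built directly from known junction coordinates (e.g.
#' coordinates read off an external alignment).
#'
#' @param replicon Replicon name.
#' @param L First retained (left-end) position, 1-based.
#' @param R Last retained (right-end) position, 1-based.
#' @param n Parental replicon length in bp.
#' @param status `"circularized"`, `"terminal_deletion_only"` or
#'   `"intact"`.
#' @param evidence Junction-evidence data frame (may be empty).
#' @param warnings Character vector of analysis warnings.
#' @return Object of class `circularization_call` with derived
#'   `left_deletion = L - 1` and `right_deletion = n - R`.
#' @export
circularization_call <- function(replicon, L, R, n,
                                 status = c("circularized",
                                            "terminal_deletion_only",
                                            "intact"),
                                 evidence = NULL, warnings = character()) {
  status <- match.arg(status)
  stopifnot(L >= 1, R <= n, L < R)
  if (status == "circularized" &&
      (is.null(evidence) || nrow(evidence) == 0L)) {
    stop("a circularized call requires junction evidence")
  }
  structure(list(replicon = replicon, L = L, R = R, n = n,
                 left_deletion = L - 1, right_deletion = n - R,
                 status = status, evidence = evidence, warnings = warnings),
            class = "circularization_call")
}

#' @export
print.circularization_call <- function(x, ...) {
  kb <- deletion_sizes_kb(x)
  cat(sprintf(
    "<circularization_call> %s: %s\n  L = %s, R = %s (n = %s)\n  deletions: left %s bp (%d kb), right %s bp (%d kb)\n  junction evidence: %d record(s)\n",
    x$replicon, x$status, format(x$L, big.mark = ","),
    format(x$R, big.mark = ","), format(x$n, big.mark = ","),
    format(x$left_deletion, big.mark = ","), kb[1],
    format(x$right_deletion, big.mark = ","), kb[2],
    if (is.null(x$evidence)) 0L else nrow(x$evidence)))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

.consensus_position <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  modal <- as.numeric(names(tab)[tab == tab[1]])
  min(modal)
}

#' Call replicon topology from boundaries and junction evidence
#'
#' The decision rule mirrors how circularization is established from
#' shotgun data: junction-spanning reads/contigs are decisive when they
#' agree among themselves and sit within `tolerance` of the
#' coverage-derived boundaries; their consensus `(L, R)` then overrides the
#' coverage cut-offs (junction coordinates are base-precise, coverage
#' boundaries are read-length-limited). Without sufficient junction
#' evidence, boundaries showing deletions yield `terminal_deletion_only` —
#' deliberately *not* a claim that the chromosome is linear, since missing
#' junction evidence does not rule circularization out. Boundaries at the
#' termini with no junctions yield `intact`.
#'
#' Evidence sufficiency: at least `min_evidence` concordant
#' junction-spanning queries, or a single query whose two anchors are both
#' at least `long_anchor` bp (one long assembled contig is as decisive as
#' multiple reads).
#'
#' @param left_boundary,right_boundary [detect_boundary()] results.
#' @param junctions [find_junctions()] result.
#' @param n Parental replicon length in bp.
#' @param tolerance Maximum distance (bp) between junction consensus and
#'   coverage boundaries (default twice the default read length).
#' @param min_evidence Minimum concordant junction queries.
#' @param long_anchor Anchor length (bp) at which a single query suffices.
#' @return A [circularization_call()].
#' @export
call_topology <- function(left_boundary, right_boundary, junctions, n,
                          tolerance = 300, min_evidence = 2,
                          long_anchor = 500) {
  replicon <- left_boundary$replicon
  warnings <- character()
  if (!is.null(junctions) && nrow(junctions)) {
    # cluster evidence by (L, R) agreement within tolerance
    ord <- order(junctions$L, junctions$R)
    j <- junctions[ord, , drop = FALSE]
    cluster <- cumsum(c(1L, abs(diff(j$L)) > tolerance |
                            abs(diff(j$R)) > tolerance))
    clusters <- split(j, cluster)
    supported <- Filter(function(cl) {
      nrow(cl) >= min_evidence ||
        any(cl$right_anchor_len >= long_anchor &
            cl$left_anchor_len >= long_anchor)
    }, clusters)
    if (length(supported) >= 2L) {
      Ls <- vapply(supported, function(cl) .consensus_position(cl$L), 0)
      Rs <- vapply(supported, function(cl) .consensus_position(cl$R), 0)
      stop("conflicting junction clusters: (L, R) = ",
           paste(sprintf("(%s, %s)", Ls, Rs), collapse = " vs "))
    }
    if (length(supported) == 1L) {
      cl <- supported[[1]]
      L <- .consensus_position(cl$L)
      R <- .consensus_position(cl$R)
      dl <- abs(L - left_boundary$position)
      dr <- abs(R - right_boundary$position)
      if (dl <= tolerance && dr <= tolerance) {
        return(circularization_call(replicon, L, R, n,
                                    status = "circularized", evidence = cl,
                                    warnings = warnings))
      }
      warnings <- c(warnings, sprintf(
        "junction consensus (L=%d, R=%d) disagrees with coverage boundaries (%d, %d) by more than %d bp; junction evidence not used",
        L, R, left_boundary$position, right_boundary$position, tolerance))
    }
  }
  L <- left_boundary$position
  R <- right_boundary$position
  if (L > 1 || R < n) {
    circularization_call(replicon, L, R, n,
                         status = "terminal_deletion_only",
                         evidence = junctions, warnings = warnings)
  } else {
    circularization_call(replicon, 1, n, status = "intact", n = n,
                         evidence = junctions, warnings = warnings)
  }
}

#' Deletion sizes in kb, rounded half away from zero
#'
#' @param call A [circularization_call()].
#' @return Numeric vector `c(left_kb, right_kb)`.
#' @export
deletion_sizes_kb <- function(call) {
  half_away <- function(x) sign(x) * floor(abs(x) / 1000 + 0.5)
  c(left_kb = half_away(call$left_deletion),
    right_kb = half_away(call$right_deletion))
}

#' Fraction of the parental genome lost by a derivative strain
#'
#' Sums whole lost replicons and the two terminal chromosomal deletions,
#' as a percentage of the parental genome size.
#'
#' @param genome Parental [genome()].
#' @param lost Character vector of names of entirely lost replicons.
#' @param call [circularization_call()] for the chromosome (supplies
#'   terminal deletion sizes); `NULL` for no chromosomal deletion.
#' @return Percent of parental genome content lost.
#' @export
genome_loss_fraction <- function(genome, lost = character(), call = NULL) {
  unknown <- setdiff(lost, names(genome$replicons))
  if (length(unknown)) stop("unknown replicon(s): ",
                            paste(unknown, collapse = ", "))
  lost_bp <- sum(vapply(genome$replicons[lost], `[[`, numeric(1), "length"))
  del_bp <- if (is.null(call)) 0 else call$left_deletion + call$right_deletion
  100 * (lost_bp + del_bp) / total_length(genome)
}
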