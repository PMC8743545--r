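#' Find the terminal inverted repeat (TIR) of a linear replicon
#'
#' Linear *Streptomyces* replicons carry inverted repeats at their two
#' ends. The finder takes the first `window` bases (the 5' probe) and the
#' reverse complement of the last `window` bases, and reports the
#' best-scoring ungapped local alignment between them (+1 match / -2
#' mismatch, no gaps: ungapped blocks keep the "number of differences"
#' well defined). Coordinates are reported in forward coordinates of the
#' replicon for both copies.
#'
#' `left_offset` is the number of left-window bases preceding the aligned
#' repeat when the right copy starts deeper than the left copy;
#' `right_truncation` is the number of bases of the idealized repeat
#' missing at the right end (the aligned left copy starts that many bases
#' after the left terminus while the right copy starts at its terminus) —
#' a right copy "missing its first 65 bp" reports `right_truncation = 65`.
#'
#' @param replicon A linear [replicon()].
#' @param window Probe window length in bp (both ends; `2 * window` must
#'   not exceed the replicon length).
#' @param min_len Minimum repeat length to report.
#' @param min_identity Minimum percent identity to report.
#' @return A list of class `tir_report` with fields `replicon`,
#'   `left_interval`, `right_interval`, `repeat_length`, `identity`
#'   (percent, rounded to integer), `differences`, `left_offset`,
#'   `right_truncation`; or `NULL` if no block passes the thresholds.
#' @export
find_tir <- function(replicon, window = 2000, min_len = 30,
                     min_identity = 90) {
  n <- replicon$length
  if (2 * window > n) stop("window too large: 2*window exceeds replicon length")
  a <- substr(replicon$sequence, 1L, window)
  b <- revcomp(substr(replicon$sequence, n - window + 1L, n))
  blk <- .best_ungapped_block(a, b)
  if (is.null(blk)) return(NULL)
  L <- blk$len
  identity <- round(100 * (1 - blk$mism / L))
  if (L < min_len || identity < min_identity) return(NULL)
  i <- blk$i; j <- blk$j
  structure(list(
    replicon = replicon$name,
    left_interval = c(i, i + L - 1L),
    right_interval = c(n - j - L + 2L, n - j + 1L),
    repeat_length = L,
    identity = identity,
    differences = blk$mism,
    left_offset = max(0L, j - i),
    right_truncation = max(0L, i - j)
  ), class = "tir_report")
}

#' @export
print.tir_report <- function(x, ...) {
  cat(sprintf(
    "<tir_report> %s: %d bp repeat, %d%% identity (%d difference(s))\n  left copy %d-%d, right copy %d-%d; left_offset %d, right_truncation %d\n",
    x$replicon, x$repeat_length, x$identity, x$differences,
    x$left_interval[1], x$left_interval[2],
    x$right_interval[1], x$right_interval[2],
    x$left_offset, x$right_truncation))
  invisible(x)
}

# Best-scoring ungapped block between strings a and b (+1/-2), found by a
# max-subarray scan of every diagonal. Returns 1-based start positions
# i (in a) and j (in b), block length and mismatch count.
.best_ungapped_block <- function(a, b, match = 1, mismatch = -2) {
  ai <- utf8ToInt(a); bi <- utf8ToInt(b)
  wa <- length(ai); wb <- length(bi)
  best <- list(score = 0, len = 0L)
  for (d in (-(wa - 1L)):(wb - 1L)) {
    i0 <- max(1L, 1L - d); i1 <- min(wa, wb - d)
    if (i1 < i0) next
    m <- ai[i0:i1] == bi[(i0 + d):(i1 + d)]
    v <- ifelse(m, match, mismatch)
    cs <- cumsum(v)
    prefix <- c(0, cs[-length(cs)])
    pmin_val <- cummin(prefix)
    val <- cs - pmin_val
    e <- which.max(val)
    score <- val[e]
    if (score <= 0) next
    s <- which.max(prefix[seq_len(e)] == pmin_val[e])  # first index at min
    len <- e - s + 1L
    if (score > best$score || (score == best$score && len > best$len)) {
      mism <- sum(!m[s:e])
      best <- list(score = score, i = i0 + s - 1L, j = i0 + s - 1L + d,
                   len = len, mism = mism)
    }
  }
  if (best$len == 0L) NULL else best
}

#' Terminal k-mers of a linear replicon
#'
#' Returns the first `k` bases and the reverse complement of the last `k`
#' bases; equality of the pair indicates a perfect terminal repeat of at
#' least `k` bp. Useful for inspecting short conserved telomeric motifs at
#' linear-replicon ends.
#'
#' @param replicon A [replicon()].
#' @param k Motif length in bp.
#' @return Named character vector `c(first = ..., last_rc = ...)`.
#' @export
terminal_motif <- function(replicon, k) {
  if (k > replicon$length) stop("k exceeds replicon length")
  c(first = substr(replicon$sequence, 1L, k),
    last_rc = revcomp(substr(replicon$sequence, replicon$length - k + 1L,
                             replicon$length)))
}
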