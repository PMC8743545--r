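#' Enumerate Cas9 protospacer candidates in a target region
#'
#' Finds every 20-mer immediately 5' of an NGG PAM, on either strand,
#' with protospacer and PAM lying wholly inside the region. High-GC
#' genomes offer NGG motifs at high frequency, so regions of ordinary gene
#' size typically yield hundreds of candidates before screening.
#'
#' `protospacer_start` is strand-oriented: the replicon coordinate of the
#' protospacer's 5' end on its own strand (for `-` candidates this is the
#' larger coordinate of the site).
#'
#' @param genome A [genome()].
#' @param replicon Replicon name containing the target region.
#' @param start,end Region interval, 1-based inclusive.
#' @return Data frame of unscreened candidates: `spacer`, `replicon`,
#'   `protospacer_start`, `strand`, `pam`, `off_target_hits` (NA until
#'   screened), `unique` (NA until screened).
#' @export
enumerate_protospacers <- function(genome, replicon, start, end) {
  r <- genome$replicons[[replicon]]
  if (is.null(r)) stop("unknown replicon '", replicon, "'")
  if (start < 1 || end > r$length || start > end) {
    stop("region out of bounds for '", replicon, "'")
  }
  seq <- substr(r$sequence, start, end)
  w <- nchar(seq)
  rows <- list()
  # + strand: spacer [p, p+19], PAM [p+20, p+22] with GG at p+21..p+22
  gg <- gregexpr("(?=GG)", seq, perl = TRUE)[[1]]
  gg <- gg[gg > 0]
  for (q in gg) {
    p <- q - 21L  # spacer start (region-local)
    if (p < 1L) next
    rows[[length(rows) + 1L]] <- data.frame(
      spacer = substr(seq, p, p + 19L), replicon = replicon,
      protospacer_start = start + p - 1L, strand = "+",
      pam = substr(seq, p + 20L, p + 22L)
    )
  }
  # - strand: CCN on + strand at [q, q+2]; spacer occupies + coords
  # [q+3, q+22], 5' end (minus-strand orientation) at + coordinate q+22
  cc <- gregexpr("(?=CC)", seq, perl = TRUE)[[1]]
  cc <- cc[cc > 0]
  for (q in cc) {
    if (q + 22L > w) next
    rows[[length(rows) + 1L]] <- data.frame(
      spacer = revcomp(substr(seq, q + 3L, q + 22L)), replicon = replicon,
      protospacer_start = start + q + 21L, strand = "-",
      pam = revcomp(substr(seq, q, q + 2L))
    )
  }
  out <- do.call(rbind, c(rows, list(data.frame(
    spacer = character(), replicon = character(),
    protospacer_start = integer(), strand = character(),
    pam = character()))))
  out$off_target_hits <- rep(NA_integer_, nrow(out))
  out$unique <- rep(NA, nrow(out))
  # deterministic order: by position then strand
  out <- out[order(out$protospacer_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all genomic sites (replicon, strand, strand-oriented start) matching the
# spacer within max_mismatches, optionally requiring an NGG PAM
.spacer_sites <- function(spacer, genome, max_mismatches, require_pam = TRUE) {
  pat <- Biostrings::DNAString(spacer)
  rcpat <- Biostrings::reverseComplement(pat)
  out <- list()
  for (r in genome$replicons) {
    subj <- Biostrings::DNAString(r$sequence)
    n <- r$length
    # + strand sites
    mp <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatches)
    s <- Biostrings::start(mp)
    s <- s[s >= 1 & s + 22 <= n]
    if (require_pam && length(s)) {
      pam_gg <- substring(r$sequence, s + 21L, s + 22L) == "GG"
      s <- s[pam_gg]
    }
    if (length(s)) {
      out[[length(out) + 1L]] <- data.frame(replicon = r$name, strand = "+",
                                            start = s)
    }
    # - strand sites: revcomp(spacer) on + strand, PAM = CC just upstream
    mm <- Biostrings::matchPattern(rcpat, subj, max.mismatch = max_mismatches)
    s <- Biostrings::start(mm)
    s <- s[s >= 4]
    if (require_pam && length(s)) {
      pam_cc <- substring(r$sequence, s - 3L, s - 2L) == "CC"
      s <- s[pam_cc]
    }
    if (length(s)) {
      out[[length(out) + 1L]] <- data.frame(replicon = r$name, strand = "-",
                                            start = s + 19L)
    }
  }
  sites <- do.call(rbind, c(out, list(data.frame(replicon = character(),
                                                 strand = character(),
                                                 start = integer()))))
  unique(sites)  # collapse coincident hits to one site
}

#' Screen a protospacer candidate for genome-wide off-targets
#'
#' Counts all genomic sites — both strands, all replicons — whose 20-mer is
#' within `max_mismatches` (Hamming distance, no gaps) of the spacer and,
#' when `require_pam`, is followed by an NGG PAM. The candidate's own
#' on-target site is excluded. A candidate is `unique` iff no off-target
#' site remains.
#'
#' @param candidate One-row candidate data frame from
#'   [enumerate_protospacers()] (or any row with `spacer`, `replicon`,
#'   `protospacer_start`, `strand`).
#' @param genome A [genome()].
#' @param max_mismatches Maximum Hamming distance for an off-target site.
#' @param require_pam Require NGG next to off-target sites (default TRUE;
#'   PAM-less matches cannot be cut by Cas9).
#' @return The candidate row with `off_target_hits` and `unique` filled in.
#' @export
screen_off_targets <- function(candidate, genome, max_mismatches = 2,
                               require_pam = TRUE) {
  sites <- .spacer_sites(candidate$spacer, genome, max_mismatches,
                         require_pam)
  own <- sites$replicon == candidate$replicon &
    sites$strand == candidate$strand &
    sites$start == candidate$protospacer_start
  candidate$off_target_hits <- nrow(sites) - sum(own)
  candidate$unique <- candidate$off_target_hits == 0L
  candidate
}

#' Design unique Cas9 spacers against a target region
#'
#' Enumerates all NGG protospacers in the region, screens each genome-wide,
#' keeps only candidates with zero off-target sites at `max_mismatches`,
#' and ranks the survivors by fewest near-miss sites at
#' `max_mismatches + 1` (a margin-of-safety criterion), then by position.
#' An empty result is a valid outcome: it means no spacer in the region is
#' free of off-target recognition sites.
#'
#' @inheritParams enumerate_protospacers
#' @param max_mismatches Off-target Hamming radius (default 2 over the full
#'   20-mer).
#' @param seed_strict If TRUE, off-target sites additionally require a
#'   perfect match over the PAM-proximal 12 bases (the Cas9 seed region);
#'   mismatch-in-seed sites are not counted. Off by default.
#' @return Data frame of unique candidates, ranked; extra column
#'   `near_miss_hits`.
#' @export
design_spacers <- function(genome, replicon, start, end, max_mismatches = 2,
                           seed_strict = FALSE) {
  cands <- enumerate_protospacers(genome, replicon, start, end)
  if (!nrow(cands)) return(cbind(cands, near_miss_hits = integer()))
  rows <- lapply(seq_len(nrow(cands)), function(i) {
    cand <- cands[i, , drop = FALSE]
    sites <- .spacer_sites(cand$spacer, genome, max_mismatches + 1L, TRUE)
    if (nrow(sites)) {
      dist <- .site_mismatches(cand$spacer, sites, genome,
                               seed_strict = seed_strict)
      sites <- sites[dist$keep, , drop = FALSE]
      dist <- dist$dist[dist$keep]
    } else dist <- integer()
    own <- sites$replicon == cand$replicon & sites$strand == cand$strand &
      sites$start == cand$protospacer_start
    cand$off_target_hits <- sum(dist[!own] <= max_mismatches)
    cand$unique <- cand$off_target_hits == 0L
    cand$near_miss_hits <- sum(dist[!own] == max_mismatches + 1L)
    cand
  })
  res <- do.call(rbind, rows)
  res <- res[res$unique, , drop = FALSE]
  res <- res[order(res$near_miss_hits, res$protospacer_start, res$strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# Hamming distance of the spacer to each site's strand-oriented 20-mer;
# with seed_strict, sites with any mismatch in the PAM-proximal 12 bases
# (positions 9-20 of the spacer) are dropped.
.site_mismatches <- function(spacer, sites, genome, seed_strict = FALSE) {
  sp <- utf8ToInt(spacer)
  dist <- integer(nrow(sites))
  keep <- rep(TRUE, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    r <- genome$replicons[[sites$replicon[i]]]
    if (sites$strand[i] == "+") {
      s20 <- substr(r$sequence, sites$start[i], sites$start[i] + 19L)
    } else {
      s20 <- revcomp(substr(r$sequence, sites$start[i] - 19L, sites$start[i]))
    }
    mism <- sp != utf8ToInt(s20)
    dist[i] <- sum(mism)
    if (seed_strict && any(mism[9:20])) keep[i] <- FALSE
  }
  list(dist = dist, keep = keep)
}
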