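#' Generate a random linear replicon, optionally with terminal inverted repeats
#'
#' Emulates a linear *Streptomyces*-style replicon: high-GC random sequence
#' whose two ends form a terminal inverted repeat (TIR) — the last
#' `tir_length` bases are exactly the reverse complement of the first
#' `tir_length` bases. `tir_length = 0` gives a plain random sequence with no
#' enforced terminal symmetry.
#'
#' @param length Replicon length in bp.
#' @param gc GC fraction in (0, 1); actinomycete genomes sit near 0.70.
#' @param tir_length TIR length in bp (must be at most `length/2`).
#' @param seed Integer seed; the same seed reproduces the replicon exactly.
#' @param name Replicon name.
#' @return A linear [replicon()].
#' @export
generate_replicon <- function(length, gc = 0.70, tir_length = 0, seed = 1,
                              name = "synthetic") {
  if (gc <= 0 || gc >= 1) stop("gc must lie strictly between 0 and 1")
  if (tir_length < 0 || 2 * tir_length > length) {
    stop("tir_length must satisfy 0 <= tir_length <= length/2")
  }
  seq <- withr::with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste0(sample(names(probs), length, replace = TRUE, prob = probs),
           collapse = "")
  })
  if (tir_length > 0) {
    prefix <- substr(seq, 1L, tir_length)
    seq <- paste0(substr(seq, 1L, length - tir_length), revcomp(prefix))
  }
  replicon(name, seq, "linear")
}

#' Specify a mutant strain derived from a parental genome
#'
#' A strain spec records the structural events observed after megaplasmid
#' curing: whole-replicon loss, and circularization of a linear replicon
#' with loss of terminal segments. It also carries per-replicon copy
#' numbers used by [simulate_reads()] to scale sequencing depth (plasmid
#' copy number per chromosome).
#'
#' @param drop Character vector of replicon names lost entirely.
#' @param circularize `NULL`, or a list/list-of-lists with fields `name`,
#'   `left_del`, `right_del`: the replicon circularizes after deleting
#'   `left_del` bp from its left end and `right_del` bp from its right end.
#' @param copy_number Named numeric vector of depth multipliers (default 1
#'   for every replicon).
#' @return An object of class `strain_spec`.
#' @export
strain_spec <- function(drop = character(), circularize = NULL,
                        copy_number = numeric()) {
  if (!is.null(circularize) && !is.null(circularize$name)) {
    circularize <- list(circularize)
  }
  for (ev in circularize) {
    stopifnot(is.character(ev$name), ev$left_del >= 0, ev$right_del >= 0)
  }
  structure(list(drop = drop, circularize = circularize,
                 copy_number = copy_number),
            class = "strain_spec")
}

#' Derive a mutant genome from a parental genome and a strain spec
#'
#' Dropped replicons are removed. A circularization event on a replicon of
#' length `n` with deletions `(dl, dr)` yields a circular replicon of length
#' `n - dl - dr` whose sequence starts at parental position `dl + 1` and
#' ends at parental position `n - dr`; the new origin is the fusion junction
#' joining parental positions `n - dr` and `dl + 1`. Untouched replicons are
#' carried over byte-identical.
#'
#' @param genome Parental [genome()].
#' @param spec A [strain_spec()].
#' @return The derived [genome()].
#' @export
derive_strain <- function(genome, spec) {
  nms <- names(genome$replicons)
  missing <- setdiff(spec$drop, nms)
  if (length(missing)) stop("cannot drop unknown replicon(s): ",
                            paste(missing, collapse = ", "))
  reps <- genome$replicons[setdiff(nms, spec$drop)]
  for (ev in spec$circularize) {
    if (!ev$name %in% names(reps)) {
      stop("circularize event on missing replicon '", ev$name, "'")
    }
    r <- reps[[ev$name]]
    if (ev$left_del + ev$right_del >= r$length) {
      stop("deletions exceed replicon length for '", ev$name, "'")
    }
    newseq <- substr(r$sequence, ev$left_del + 1L, r$length - ev$right_del)
    reps[[ev$name]] <- replicon(r$name, newseq, "circular")
  }
  chrom <- if (genome$chromosome_name %in% names(reps)) {
    genome$chromosome_name
  } else NULL
  genome(unname(reps), chrom)
}

# substitute bases in-place at a global per-base rate; returns mutated
# strings plus per-read error counts (vectorized over a single raw buffer)
.mutate_reads <- function(seqs, rate) {
  nerr <- integer(length(seqs))
  if (rate <= 0 || !length(seqs)) return(list(seqs = seqs, nerr = nerr))
  buf <- charToRaw(paste0(seqs, collapse = ""))
  total <- rbinom(1L, length(buf), rate)
  if (total > 0) {
    pos <- sample.int(length(buf), total)
    bases <- charToRaw("ACGT")
    idx <- match(buf[pos], bases)
    buf[pos] <- bases[((idx - 1L + sample.int(3L, total, replace = TRUE)) %% 4L) + 1L]
    bounds <- c(0, cumsum(nchar(seqs)))
    nerr <- tabulate(findInterval(pos - 0.5, bounds), nbins = length(seqs))
    big <- rawToChar(buf)
    ends <- bounds[-1]
    seqs <- substring(big, bounds[-length(bounds)] + 1, ends)
  }
  list(seqs = seqs, nerr = nerr)
}

#' Simulate paired-end shotgun reads from a genome
#'
#' Fragments are drawn per replicon at Poisson-distributed counts with
#' expectation `depth * n / (2 * read_len)` pairs, insert sizes
#' Normal(`insert_mean`, `insert_sd`) truncated below at `read_len`, and
#' uniform substitution errors at rate `sub_error`. Linear replicons sample
#' fragments wholly inside `[1, n]`, which mechanically depresses coverage
#' at the termini — the terminal-under-coverage signature real short-read
#' data shows at linear-replicon ends. Circular replicons sample fragments
#' across the origin. Per-replicon depth is `mean_depth` scaled by the
#' strain spec's copy number (plasmids at 2 copies per chromosome get twice
#' the chromosome depth).
#'
#' @param genome A [genome()] (typically a derived mutant strain).
#' @param mean_depth Mean fold-coverage at copy number 1.
#' @param read_len Read length in bp.
#' @param insert_mean,insert_sd Insert-size distribution (bp).
#' @param sub_error Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed; identical inputs and seed give byte-identical
#'   output.
#' @param copy_number Named depth multipliers (overrides 1x default).
#' @return List with `reads` (data frame: `id`, `sequence`, `mate`) and
#'   `truth` (data frame: `read_id`, `replicon`, `start`, `strand`,
#'   `errors`) giving the true source interval of every read; `start` is
#'   the 1-based source position of the read's leftmost aligned base.
#' @export
simulate_reads <- function(genome, mean_depth = 50, read_len = 150,
                           insert_mean = 300, insert_sd = 30,
                           sub_error = 0.01, seed = 1,
                           copy_number = numeric()) {
  if (sub_error < 0 || sub_error >= 1) stop("sub_error must be in [0, 1)")
  if (mean_depth < 0) stop("mean_depth must be >= 0")
  if (read_len > insert_mean) stop("read_len must not exceed insert_mean")
  withr::with_seed(seed, {
    out_reads <- list(); out_truth <- list()
    for (r in genome$replicons) {
      cn <- if (r$name %in% names(copy_number)) copy_number[[r$name]] else 1
      np <- rpois(1L, cn * mean_depth * r$length / (2 * read_len))
      if (np == 0L) next
      n <- r$length
      frag <- pmax(round(rnorm(np, insert_mean, insert_sd)), read_len)
      if (r$topology == "circular") {
        frag <- pmin(frag, n)
        start <- 1L + floor(runif(np) * n)
        src <- paste0(r$sequence, substr(r$sequence, 1L, max(frag)))
      } else {
        frag <- pmin(frag, n)
        start <- 1L + floor(runif(np) * (n - frag + 1))
        src <- r$sequence
      }
      r1 <- substring(src, start, start + read_len - 1L)
      p2 <- start + frag - read_len
      r2 <- revcomp(substring(src, p2, p2 + read_len - 1L))
      m1 <- .mutate_reads(r1, sub_error)
      m2 <- .mutate_reads(r2, sub_error)
      ids <- sprintf("%s_p%06d", r$name, seq_len(np))
      out_reads[[r$name]] <- data.frame(
        id = c(paste0(ids, "/1"), paste0(ids, "/2")),
        sequence = c(m1$seqs, m2$seqs),
        mate = rep(c("1", "2"), each = np)
      )
      out_truth[[r$name]] <- data.frame(
        read_id = c(paste0(ids, "/1"), paste0(ids, "/2")),
        replicon = r$name,
        start = c((start - 1L) %% n + 1L, (p2 - 1L) %% n + 1L),
        strand = rep(c("+", "-"), each = np),
        errors = c(m1$nerr, m2$nerr)
      )
    }
    reads <- do.call(rbind, c(out_reads, list(.empty_reads())))
    truth <- do.call(rbind, c(out_truth, list(.empty_truth())))
    rownames(reads) <- rownames(truth) <- NULL
    list(reads = reads, truth = truth)
  })
}

.empty_reads <- function() {
  data.frame(id = character(), sequence = character(), mate = character())
}
.empty_truth <- function() {
  data.frame(read_id = character(), replicon = character(), start = integer(),
             strand = character(), errors = integer())
}

#' Desk-scale fixture genome and cured-strain spec
#'
#' A reduced stand-in for a multi-replicon linear genome that preserves the
#' size hierarchy of a *Streptomyces*-like strain: a 500 kb linear
#' "chromosome", a 50 kb linear megaplasmid at 1 copy per chromosome, and a
#' 5 kb linear small plasmid at 2 copies per chromosome, all with 400 bp
#' TIRs and GC 0.70.
#'
#' `fixture_cured_spec()` is the matching megaplasmid-cured mutant: the
#' megaplasmid is lost and the chromosome circularizes with terminal
#' deletions of 7,334 bp (left) and 8,588 bp (right) — the deletions scaled
#' proportionally from a circularized clone with ~99 kb and ~116 kb
#' deletions on a 6.75 Mb chromosome.
#'
#' @param seed Integer seed for the random sequences.
#' @return `fixture_genome()`: a [genome()]; `fixture_cured_spec()`: a
#'   [strain_spec()]; `fixture_copy_number()`: named depth multipliers.
#' @export
fixture_genome <- function(seed = 1) {
  genome(list(
    generate_replicon(500000L, gc = 0.70, tir_length = 400L,
                      seed = seed, name = "chr"),
    generate_replicon(50000L, gc = 0.70, tir_length = 400L,
                      seed = seed + 1L, name = "megaplasmid"),
    generate_replicon(5000L, gc = 0.70, tir_length = 400L,
                      seed = seed + 2L, name = "small_plasmid")
  ), chromosome_name = "chr")
}

#' @rdname fixture_genome
#' @export
fixture_cured_spec <- function() {
  strain_spec(
    drop = "megaplasmid",
    circularize = list(name = "chr", left_del = 7334L, right_del = 8588L),
    copy_number = fixture_copy_number()
  )
}

#' @rdname fixture_genome
#' @export
fixture_copy_number <- function() {
  c(chr = 1, megaplasmid = 1, small_plasmid = 2)
}
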