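# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own algorithms.

random_dna <- function(n, gc = 0.5, seed = NULL) {
  draw <- function() paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                                   prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                            (1 - gc) / 2)), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

oracle_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(x, "")[[1]]]), collapse = "")
}

# Plant a TIR of tir_len with exactly m internal mismatches into a random
# sequence, guarding the block boundary so the repeat cannot extend by a
# lucky base match: the base just inside position tir_len + 1 is forced to
# mismatch its would-be partner.
plant_tir <- function(n, tir_len, m = 0, seed = 1) {
  withr::with_seed(seed, {
    chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    # right end = revcomp(left end) over tir_len bases
    chars[(n - tir_len + 1):n] <- rev(comp[chars[1:tir_len]])
    # guard: position tir_len+1 from the left must NOT pair with its
    # counterpart at n - tir_len (which would extend the repeat)
    partner <- comp[chars[n - tir_len]]
    if (chars[tir_len + 1] == partner) {
      chars[tir_len + 1] <- sample(setdiff(c("A", "C", "G", "T"), partner), 1)
    }
    # introduce m mismatches inside the right-hand copy; keep them >= 3
    # bases away from the block edges so the optimal ungapped block is
    # still the full planted repeat (a mismatch within 2 bp of an edge
    # makes the trimmed block score higher)
    if (m > 0) {
      pos <- sample((n - tir_len + 4):(n - 3), m)
      for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                chars[p]), 1)
    }
    paste0(chars, collapse = "")
  })
}

# Fully independent cubic best-ungapped-block oracle (+1/-2): enumerate all
# (i, j, L) triples. Only usable for small windows.
oracle_best_block <- function(a, b, match = 1, mismatch = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- list(score = -Inf)
  for (i in seq_along(av)) {
    for (j in seq_along(bv)) {
      sc <- 0; mm <- 0
      Lmax <- min(length(av) - i, length(bv) - j) + 1
      for (L in seq_len(Lmax)) {
        if (av[i + L - 1] == bv[j + L - 1]) sc <- sc + match
        else { sc <- sc + mismatch; mm <- mm + 1 }
        if (sc > best$score ||
            (sc == best$score && L > best$len)) {
          best <- list(score = sc, i = i, j = j, len = L, mism = mm)
        }
      }
    }
  }
  best
}

# Quadratic per-diagonal oracle via prefix sums (structured differently
# from the implementation's scan); usable at 2 kb windows.
oracle_best_block_quadratic <- function(a, b, match = 1, mismatch = -2) {
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  wa <- length(av); wb <- length(bv)
  best <- list(score = -Inf, len = 0L)
  for (d in (-(wa - 1)):(wb - 1)) {
    i0 <- max(1, 1 - d); i1 <- min(wa, wb - d)
    if (i1 < i0) next
    v <- ifelse(av[i0:i1] == bv[(i0:i1) + d], match, mismatch)
    cs <- c(0, cumsum(v))
    minpos <- 1; minval <- 0
    for (e in 2:length(cs)) {
      sc <- cs[e] - minval
      len <- e - minpos
      if (sc > best$score || (sc == best$score && len > best$len)) {
        best <- list(score = sc, i = i0 + minpos - 1, j = i0 + minpos - 1 + d,
                     len = len,
                     mism = sum(v[minpos:(e - 1)] == mismatch))
      }
      if (cs[e] < minval) { minval <- cs[e]; minpos <- e }
    }
  }
  if (best$len == 0) NULL else best
}

# Brute-force genome-wide NGG-protospacer scan: all 20-mers 5' of an NGG on
# both strands, with strand-oriented start coordinates. Vectorized straight
# from the definition so it stays usable at 100 kb.
oracle_pam_sites <- function(genome) {
  rc_many <- function(x) {
    vapply(x, function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s),
                                             "")[[1]]), collapse = ""),
           character(1), USE.NAMES = FALSE)
  }
  out <- list()
  for (r in genome$replicons) {
    s <- r$sequence; n <- nchar(s)
    if (n < 23) next
    p <- seq_len(n - 22)
    plus <- p[substring(s, p + 21, p + 22) == "GG"]
    if (length(plus)) {
      out[[length(out) + 1]] <- data.frame(
        replicon = r$name, strand = "+", start = plus,
        seq20 = substring(s, plus, plus + 19))
    }
    q <- seq_len(n - 22)
    minus <- q[substring(s, q, q + 1) == "CC"]
    if (length(minus)) {
      out[[length(out) + 1]] <- data.frame(
        replicon = r$name, strand = "-", start = minus + 22,
        seq20 = rc_many(substring(s, minus + 3, minus + 22)))
    }
  }
  do.call(rbind, c(out, list(data.frame(replicon = character(),
                                        strand = character(),
                                        start = integer(),
                                        seq20 = character()))))
}

oracle_site_distances <- function(spacer, sites) {
  sp <- utf8ToInt(spacer)
  vapply(sites$seq20, function(x) sum(utf8ToInt(x) != sp), 0L,
         USE.NAMES = FALSE)
}

oracle_hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

oracle_offtarget_count <- function(candidate, sites, max_mismatches) {
  d <- vapply(sites$seq20, oracle_hamming, 0L, a = candidate$spacer,
              USE.NAMES = FALSE)
  own <- sites$replicon == candidate$replicon &
    sites$strand == candidate$strand &
    sites$start == candidate$protospacer_start
  sum(d <= max_mismatches & !own)
}

# small multi-replicon genome for fast unit tests (no TIRs by default so
# mapping tests are unambiguous)
small_genome <- function(seed = 1, tir = 0) {
  genome(list(
    generate_replicon(30000L, gc = 0.7, tir_length = tir, seed = seed,
                      name = "chr"),
    generate_replicon(8000L, gc = 0.7, tir_length = tir, seed = seed + 1L,
                      name = "plasA"),
    generate_replicon(3000L, gc = 0.7, tir_length = tir, seed = seed + 2L,
                      name = "plasB")
  ), chromosome_name = "chr")
}

make_profile <- function(name, depth) {
  structure(list(replicon = name, depth = as.integer(depth),
                 n = length(depth)),
            class = "coverage_profile")
}
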