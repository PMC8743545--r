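#' @useDynLib replitopo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rbinom rnorm rpois runif
#' @importFrom utils head read.delim write.table
NULL

# All coordinates at every interface of this package are 1-based inclusive,
# matching the convention of genome-browser positions and SAM POS.

.valid_dna <- function(x) {
  !is.na(x) && nzchar(x) && !grepl("[^ACGT]", x)
}

#' Create a replicon
#'
#' A replicon is a single independently replicating DNA molecule (chromosome
#' or plasmid) with a declared topology. Linear replicons are the default:
#' linear chromosomes and linear plasmids with terminal inverted repeats are
#' the norm in *Streptomyces* and relatives.
#'
#' @param name Replicon identifier (unique within a genome).
#' @param sequence DNA string over the strict alphabet `{A,C,G,T}`.
#'   Lower-case input is accepted and upper-cased; ambiguity codes such as
#'   `N` are rejected because downstream exact k-mer logic assumes a 4-letter
#'   alphabet (pre-mask real data before ingest).
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class `replicon` with fields `name`, `sequence`,
#'   `topology` and `length`.
#' @export
replicon <- function(name, sequence, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("replicon name must be a non-empty string")
  }
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || !.valid_dna(sequence)) {
    stop("replicon '", name, "': sequence must be non-empty over {A,C,G,T}; ",
         "ambiguity codes (e.g. N) are not accepted")
  }
  structure(
    list(name = name, sequence = sequence, topology = topology,
         length = nchar(sequence)),
    class = "replicon"
  )
}

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf("<replicon> %s: %s, %s bp\n", x$name, x$topology,
              format(x$length, big.mark = ",")))
  invisible(x)
}

#' Create a multi-replicon genome
#'
#' @param replicons List of [replicon()] objects, order preserved.
#' @param chromosome_name Name of the replicon used as the normalization
#'   reference for copy-number ratios. Defaults to the largest replicon.
#' @return An object of class `genome` with named element `replicons`
#'   (a named list) and `chromosome_name`.
#' @export
genome <- function(replicons, chromosome_name = NULL) {
  if (!length(replicons)) stop("a genome needs at least one replicon")
  stopifnot(all(vapply(replicons, inherits, logical(1), "replicon")))
  nms <- vapply(replicons, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate replicon name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(replicons) <- nms
  if (is.null(chromosome_name)) {
    chromosome_name <- nms[which.max(vapply(replicons, `[[`, numeric(1), "length"))]
  }
  if (!chromosome_name %in% nms) {
    stop("chromosome_name '", chromosome_name, "' is not a replicon in this genome")
  }
  structure(list(replicons = replicons, chromosome_name = chromosome_name),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %d replicon(s), total %s bp (chromosome: %s)\n",
              length(x$replicons), format(total_length(x), big.mark = ","),
              x$chromosome_name))
  for (r in x$replicons) print(r)
  invisible(x)
}

#' Total genome length in bp
#' @param genome A [genome()].
#' @return Sum of member replicon lengths.
#' @export
total_length <- function(genome) {
  sum(vapply(genome$replicons, `[[`, numeric(1), "length"))
}

#' Read a multi-record FASTA file into a genome
#'
#' Topology is not representable in FASTA; it comes from a sidecar key-value
#' config (see [read_topology_config()]) or the `topology` argument. Record
#' ids are truncated at the first whitespace.
#'
#' @param path FASTA file.
#' @param chromosome_name Chromosome designation (default: largest replicon).
#' @param topology Either a single topology applied to all replicons, or a
#'   named character vector mapping replicon name to `"linear"`/`"circular"`.
#'   Unlisted replicons default to linear.
#' @return A [genome()].
#' @export
read_fasta <- function(path, chromosome_name = NULL, topology = "linear") {
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  nms <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  reps <- lapply(seq_along(seqs), function(i) {
    topo <- if (length(topology) == 1L && is.null(names(topology))) {
      topology
    } else if (nms[i] %in% names(topology)) {
      topology[[nms[i]]]
    } else "linear"
    replicon(nms[i], seqs[i], topo)
  })
  genome(reps, chromosome_name)
}

#' Write a genome to FASTA
#' @param genome A [genome()].
#' @param path Output file.
#' @export
write_fasta <- function(genome, path) {
  seqs <- vapply(genome$replicons, `[[`, character(1), "sequence")
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(genome$replicons)
  Biostrings::writeXStringSet(set, path, format = "fasta", width = 70L)
  invisible(path)
}

#' Read/write sequencing reads as FASTQ
#'
#' Reads are held as a data frame with columns `id`, `sequence` and `mate`
#' (`1`, `2` or `unpaired`). Base qualities are not modeled anywhere in this
#' package; written FASTQ carries a constant placeholder quality.
#'
#' @param path FASTQ file.
#' @param mate Mate label to assign to all records in the file.
#' @return Data frame with columns `id`, `sequence`, `mate`.
#' @export
read_fastq <- function(path, mate = "unpaired") {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = names(set), sequence = as.character(set),
             mate = rep(mate, length(set)))
}

#' @rdname read_fastq
#' @param reads Data frame with at least `id` and `sequence`.
#' @export
write_fastq <- function(reads, path) {
  if (!nrow(reads)) {
    # Biostrings refuses empty fastq sets; an empty file is the valid output
    file.create(path)
    return(invisible(path))
  }
  set <- Biostrings::DNAStringSet(reads$sequence)
  names(set) <- reads$id
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a replicon-topology sidecar config
#'
#' Flat `key=value` file: one `name=linear|circular` line per replicon plus
#' an optional `chromosome=<name>` line. Blank lines and `#` comments are
#' ignored.
#'
#' @param path Config file.
#' @return List with `topology` (named character vector) and
#'   `chromosome_name` (or `NULL`).
#' @export
read_topology_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[[`, character(1), 2L))
  chrom <- if ("chromosome" %in% keys) vals[match("chromosome", keys)] else NULL
  topo <- vals[keys != "chromosome"]
  names(topo) <- keys[keys != "chromosome"]
  if (length(topo) && !all(topo %in% c("linear", "circular"))) {
    stop("topology values must be 'linear' or 'circular'")
  }
  list(topology = topo, chromosome_name = chrom)
}

# ---- SAM ----------------------------------------------------------------

.cigar_lengths <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  if (ops[1] == -1) stop("unparseable CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^\\d+", "", toks)
  if (any(op %in% c("N", "H", "P"))) {
    stop("unsupported CIGAR op in '", cigar, "' (supported: M/=/X/I/D/S)")
  }
  list(
    ref_span = sum(n[op %in% c("M", "=", "X", "D")]),
    query_aln = sum(n[op %in% c("M", "=", "X", "I")]),
    clip_left = if (op[1] == "S") n[1] else 0L,
    clip_right = if (op[length(op)] == "S") n[length(n)] else 0L
  )
}

#' Import alignments from a SAM file
#'
#' A deliberately minimal SAM reader for the dialect this pipeline needs:
#' only QNAME, FLAG, RNAME, POS, CIGAR (ops M/=/X/I/D/S) and the `NM`/`SA`
#' tags are consumed; qualities and mate fields are ignored. Unmapped lines
#' are dropped. Supplementary alignments (flag 0x800, used by split-capable
#' mappers for chimeric reads) get `role = "supplementary"`.
#'
#' Query intervals are reported on the read *as given to the mapper*: for
#' reverse-strand lines, soft-clip lengths are mirrored so that
#' `qstart`/`qend` refer to the original read orientation.
#'
#' @param path SAM file with an `@SQ` header.
#' @param genome A [genome()]; header names/lengths must match.
#' @return Alignment-segment data frame (see [map_reads()] for columns).
#' @export
read_sam <- function(path, genome) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "@")]
  aln <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  for (h in sq) {
    fields <- strsplit(h, "\t", fixed = TRUE)[[1]]
    sn <- sub("^SN:", "", grep("^SN:", fields, value = TRUE)[1])
    ln <- as.numeric(sub("^LN:", "", grep("^LN:", fields, value = TRUE)[1]))
    if (!sn %in% names(genome$replicons)) {
      stop("SAM header sequence '", sn, "' not present in genome")
    }
    if (!is.na(ln) && ln != genome$replicons[[sn]]$length) {
      stop("SAM header length for '", sn, "' (", ln,
           ") does not match genome (", genome$replicons[[sn]]$length, ")")
    }
  }
  if (!length(aln)) return(.empty_segments())
  recs <- strsplit(aln, "\t", fixed = TRUE)
  out <- lapply(recs, function(f) {
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) return(NULL)  # unmapped
    rname <- f[3]
    if (!rname %in% names(genome$replicons)) {
      stop("alignment references unknown sequence '", rname, "'")
    }
    cg <- .cigar_lengths(f[6])
    pos <- as.integer(f[4])
    strand <- if (bitwAnd(flag, 16L) != 0L) "-" else "+"
    qlen <- cg$clip_left + cg$query_aln + cg$clip_right
    # SAM stores SEQ/clips in reference orientation; mirror for '-' strand
    qstart <- if (strand == "+") cg$clip_left + 1L else cg$clip_right + 1L
    nm <- grep("^NM:i:", f, value = TRUE)
    sup <- bitwAnd(flag, 2048L) != 0L
    data.frame(
      query_id = f[1], qstart = qstart, qend = qstart + cg$query_aln - 1L,
      qlen = qlen, replicon = rname, rstart = pos,
      rend = pos + cg$ref_span - 1L, strand = strand,
      edit_distance = if (length(nm)) as.integer(sub("^NM:i:", "", nm[1])) else 0L,
      role = if (sup) "supplementary" else "primary",
      ambiguous = FALSE
    )
  })
  segs <- do.call(rbind, out)
  if (is.null(segs)) return(.empty_segments())
  for (i in seq_len(nrow(segs))) {
    n <- genome$replicons[[segs$replicon[i]]]$length
    if (segs$rstart[i] < 1L || segs$rend[i] > n) {
      stop("alignment for '", segs$query_id[i], "' extends past replicon end")
    }
  }
  rownames(segs) <- NULL
  segs
}

.empty_segments <- function() {
  data.frame(query_id = character(), qstart = integer(), qend = integer(),
             qlen = integer(), replicon = character(), rstart = integer(),
             rend = integer(), strand = character(), edit_distance = integer(),
             role = character(), ambiguous = logical())
}

#' Export alignment segments as SAM
#'
#' The inverse of [read_sam()] for this package's minimal dialect: emits an
#' `@SQ` header from the genome, one line per segment with soft-clipped
#' CIGAR, `NM` edit-distance tag and `*` SEQ/QUAL.
#'
#' @param segments Alignment-segment data frame.
#' @param genome A [genome()].
#' @param path Output SAM file.
#' @export
write_sam <- function(segments, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (r in genome$replicons) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", r$name, r$length), con)
  }
  if (nrow(segments)) {
    flag <- ifelse(segments$strand == "-", 16L, 0L) +
      ifelse(segments$role == "supplementary", 2048L, 0L)
    alen <- segments$qend - segments$qstart + 1L
    lclip <- segments$qstart - 1L
    rclip <- segments$qlen - segments$qend
    # mirror clips into reference orientation for '-' strand lines
    sam_l <- ifelse(segments$strand == "-", rclip, lclip)
    sam_r <- ifelse(segments$strand == "-", lclip, rclip)
    cigar <- paste0(ifelse(sam_l > 0, paste0(sam_l, "S"), ""),
                    alen, "M",
                    ifelse(sam_r > 0, paste0(sam_r, "S"), ""))
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*\tNM:i:%d",
                       segments$query_id, flag, segments$replicon,
                       segments$rstart, cigar, segments$edit_distance), con)
  }
  invisible(path)
}

#' Reverse complement of a DNA string
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
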