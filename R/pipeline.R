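#' Pipeline parameter set
#'
#' Collects every tunable stage parameter with its default. Defaults are
#' sized for short-read data (150-250 bp reads) on desk-scale to
#' full-size bacterial genomes; see the methods vignette for rationale.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(
    k = 31,                    # mapper seed length
    min_anchor = 50,           # bp; minimum alignment-segment length
    max_mismatch_rate = 0.05,  # mapper mismatch tolerance
    end_trim = 150,            # bp trimmed per end for depth means
    min_depth_presence = 1,    # depth defining "covered" for breadth
    present_breadth_min = 0.95,
    absent_breadth_max = 0.05,
    boundary_min_depth = 2,    # depth defining "covered" for boundaries
    boundary_min_run = 100,    # bp; sustained-run length for boundaries
    terminal_dip = 300,        # bp; snap-to-terminus tolerance
    max_junction_gap = 10,     # bp; query-interval gap between anchors
    terminal_window = 200000,  # bp; anchor search window at each end
    tolerance = 300,           # bp; junction vs boundary agreement
    min_evidence = 2,          # concordant junction queries needed
    long_anchor = 500,         # bp; single-query (contig) sufficiency
    tir_window = 2000,         # bp; TIR probe window
    tir_min_len = 30,
    tir_min_identity = 90
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(over)] <- over
  p
}

#' Run the full per-strain analysis pipeline
#'
#' Orchestrates mapping (built-in mapper, or externally supplied
#' segments), coverage, the replicon census (presence/absence and copy
#' number), topology calling (terminal boundaries, junction evidence,
#' circularization) for every linear replicon still detectable, and TIR
#' detection on the reference replicons. Deterministic given identical
#' inputs and parameters.
#'
#' @param reference Parental reference [genome()].
#' @param reads Reads data frame (`id`, `sequence`), or `NULL` when
#'   `segments` are supplied.
#' @param segments Pre-computed alignment segments (e.g. from
#'   [read_sam()]); computed with [map_reads()] when `NULL`.
#' @param sample_id Sample label for the report.
#' @param params [pipeline_params()].
#' @param output_dir If non-NULL, report tables are written there (see
#'   [write_strain_report()]).
#' @return Object of class `strain_report`: `sample_id`, `params`,
#'   `census`, `boundaries`, `junctions`, `topology` (named list of
#'   circularization calls), `tir` (named list of TIR reports or NULL),
#'   `warnings`.
#' @export
run_pipeline <- function(reference, reads = NULL, segments = NULL,
                         sample_id = "sample", params = pipeline_params(),
                         output_dir = NULL) {
  if (is.null(segments)) {
    if (is.null(reads)) stop("run_pipeline: supply reads or segments")
    segments <- tryCatch(
      map_reads(reference, reads, k = params$k,
                min_anchor = params$min_anchor,
                max_mismatch_rate = params$max_mismatch_rate),
      error = function(e) stop("mapping stage: ", conditionMessage(e)))
  }
  warnings <- character()
  n_ambig <- sum(segments$ambiguous)
  if (n_ambig > 0) {
    warnings <- c(warnings, sprintf(
      "%d read(s) with ambiguous placement (excluded from junction evidence)",
      n_ambig))
  }

  profiles <- tryCatch(coverage_profiles(segments, reference),
                       error = function(e) stop("coverage stage: ",
                                                conditionMessage(e)))
  census <- tryCatch(
    copy_number(profiles, reference$chromosome_name,
                end_trim = params$end_trim,
                min_depth = params$min_depth_presence,
                present_breadth_min = params$present_breadth_min,
                absent_breadth_max = params$absent_breadth_max),
    error = function(e) stop("census stage: ", conditionMessage(e)))

  topology <- list(); boundaries <- list(); junctions <- list()
  for (r in reference$replicons) {
    status <- census$status[census$replicon == r$name]
    if (r$topology != "linear" || status == "absent") next
    bl <- detect_boundary(profiles[[r$name]], "left",
                          min_depth = params$boundary_min_depth,
                          min_run = params$boundary_min_run,
                          terminal_dip = params$terminal_dip)
    br <- detect_boundary(profiles[[r$name]], "right",
                          min_depth = params$boundary_min_depth,
                          min_run = params$boundary_min_run,
                          terminal_dip = params$terminal_dip)
    jx <- find_junctions(segments[segments$replicon == r$name, , drop = FALSE],
                         r, min_anchor = params$min_anchor,
                         max_junction_gap = params$max_junction_gap,
                         terminal_window = params$terminal_window)
    call <- tryCatch(
      call_topology(bl, br, jx, r$length, tolerance = params$tolerance,
                    min_evidence = params$min_evidence,
                    long_anchor = params$long_anchor),
      error = function(e) stop("topology stage (", r$name, "): ",
                               conditionMessage(e)))
    # stray coverage beyond the called boundaries: surfaced as a warning,
    # never as a rearrangement call
    d <- profiles[[r$name]]$depth
    outside <- c(if (call$L > 1) d[seq_len(call$L - 1L)],
                 if (call$R < r$length) d[(call$R + 1L):r$length])
    if (length(outside) && any(outside >= params$boundary_min_depth)) {
      warnings <- c(warnings, sprintf(
        "%s: unexplained coverage beyond called boundaries (%d position(s)); possible unresolved rearrangement",
        r$name, sum(outside >= params$boundary_min_depth)))
    }
    if (length(call$warnings)) {
      warnings <- c(warnings, paste0(r$name, ": ", call$warnings))
    }
    boundaries[[r$name]] <- list(left = bl, right = br)
    junctions[[r$name]] <- jx
    topology[[r$name]] <- call
  }

  tir <- list()
  for (r in reference$replicons) {
    if (r$topology != "linear") next
    w <- min(params$tir_window, floor(r$length / 2))
    tir[[r$name]] <- find_tir(r, window = w, min_len = params$tir_min_len,
                              min_identity = params$tir_min_identity)
  }

  report <- structure(
    list(sample_id = sample_id, params = params, census = census,
         boundaries = boundaries, junctions = junctions, topology = topology,
         tir = tir, warnings = warnings),
    class = "strain_report")
  if (!is.null(output_dir)) write_strain_report(report, output_dir)
  report
}

#' @export
print.strain_report <- function(x, ...) {
  cat("== strain report:", x$sample_id, "==\n\nReplicon census:\n")
  print(x$census, digits = 4)
  cat("\nTopology calls:\n")
  for (call in x$topology) print(call)
  cat("\nTIRs detected on reference replicons:\n")
  any_tir <- FALSE
  for (nm in names(x$tir)) {
    if (!is.null(x$tir[[nm]])) { print(x$tir[[nm]]); any_tir <- TRUE }
  }
  if (!any_tir) cat("  none\n")
  if (length(x$warnings)) {
    cat("\nWarnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}

#' Write a strain report as plain-text tables
#'
#' Emits `census.tsv`, `boundaries.tsv`, `junctions.tsv`, `tir.tsv`, a
#' human-readable `report.txt` (including every parameter used, so a run
#' can be reproduced from its own output), all diff-able.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @export
write_strain_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  cens <- report$census
  cens$mean_depth <- sprintf("%.4f", cens$mean_depth)
  cens$ratio_vs_chromosome <- sprintf("%.4f", cens$ratio_vs_chromosome)
  cens$breadth <- sprintf("%.6f", cens$breadth)
  tsv(cens, "census.tsv")
  brows <- do.call(rbind, lapply(report$boundaries, function(b) {
    data.frame(replicon = b$left$replicon,
               left = b$left$position, right = b$right$position,
               left_support = sprintf("%.2f", b$left$support_depth),
               right_support = sprintf("%.2f", b$right$support_depth))
  }))
  tsv(if (is.null(brows)) data.frame() else brows, "boundaries.tsv")
  jrows <- do.call(rbind, lapply(names(report$junctions), function(nm) {
    j <- report$junctions[[nm]]
    if (nrow(j)) cbind(replicon = nm, j) else NULL
  }))
  tsv(if (is.null(jrows)) data.frame() else jrows, "junctions.tsv")
  trows <- do.call(rbind, lapply(names(report$tir), function(nm) {
    t <- report$tir[[nm]]
    if (is.null(t)) return(NULL)
    data.frame(replicon = nm, left_start = t$left_interval[1],
               left_end = t$left_interval[2],
               right_start = t$right_interval[1],
               right_end = t$right_interval[2],
               repeat_length = t$repeat_length, identity = t$identity,
               differences = t$differences, left_offset = t$left_offset,
               right_truncation = t$right_truncation)
  }))
  tsv(if (is.null(trows)) data.frame() else trows, "tir.tsv")
  con <- file(file.path(dir, "report.txt"), "w")
  on.exit(close(con))
  writeLines(c(paste("sample:", report$sample_id), "", "parameters:"), con)
  for (nm in names(report$params)) {
    writeLines(sprintf("  %s = %s", nm, format(report$params[[nm]])), con)
  }
  writeLines("", con)
  for (call in report$topology) {
    kb <- deletion_sizes_kb(call)
    loss <- sprintf(
      "%s: status=%s L=%d R=%d left_deletion=%d (%d kb) right_deletion=%d (%d kb) evidence=%d",
      call$replicon, call$status, call$L, call$R, call$left_deletion, kb[1],
      call$right_deletion, kb[2],
      if (is.null(call$evidence)) 0L else nrow(call$evidence))
    writeLines(loss, con)
  }
  if (length(report$warnings)) {
    writeLines(c("", "warnings:", paste(" -", report$warnings)), con)
  }
  invisible(dir)
}
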