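test_that("boundaries of a fully covered replicon are its termini", {
  p <- make_profile("chr", rep(30L, 10000))
  bl <- detect_boundary(p, "left")
  br <- detect_boundary(p, "right")
  expect_equal(bl$position, 1)
  expect_equal(br$position, 10000)
})

test_that("terminal deletions produce sharp coverage boundaries", {
  d <- c(rep(0L, 2000), rep(25L, 6000), rep(0L, 2000))
  p <- make_profile("chr", d)
  expect_equal(detect_boundary(p, "left")$position, 2001)
  expect_equal(detect_boundary(p, "right")$position, 8000)
})

test_that("stray coverage peaks beyond the boundary are tolerated", {
  d <- c(rep(0L, 1000), rep(8L, 30), rep(0L, 970), rep(25L, 7000),
         rep(0L, 1000))
  p <- make_profile("chr", d)
  # the 30 bp blip at 1001 does not open a sustained run
  expect_equal(detect_boundary(p, "left", min_run = 100)$position, 2001)
})

test_that("terminal dips within tolerance snap to the terminus", {
  d <- c(rep(0L, 120), rep(25L, 9760), rep(0L, 120))
  p <- make_profile("chr", d)
  expect_equal(detect_boundary(p, "left", terminal_dip = 300)$position, 1)
  expect_equal(detect_boundary(p, "right", terminal_dip = 300)$position,
               10000)
  # but a genuine deletion larger than the tolerance does not snap
  expect_equal(detect_boundary(p, "left", terminal_dip = 50)$position, 121)
})

test_that("an effectively absent replicon raises an error", {
  p <- make_profile("gone", rep(0L, 5000))
  expect_error(detect_boundary(p, "left"), "absent")
})

test_that("the zero-deletion chimera yields junction R=n, L=1, gap 0", {
  g <- small_genome(seed = 50)
  chr <- g$replicons$chr
  n <- chr$length
  chim <- paste0(substr(chr$sequence, n - 149, n),
                 substr(chr$sequence, 1, 150))
  segs <- map_query(chim, g)
  j <- find_junctions(segs, chr)
  expect_equal(nrow(j), 1)
  expect_equal(j$R, n)
  expect_equal(j$L, 1)
  expect_equal(j$junction_gap, 0)
})

test_that("two anchors at the same end are not junction evidence", {
  g <- small_genome(seed = 51)
  chr <- g$replicons$chr
  # chimera of two left-end loci: both anchors at the left end
  chim <- paste0(substr(chr$sequence, 1, 150),
                 substr(chr$sequence, 5000, 5149))
  segs <- map_query(chim, g)
  j <- find_junctions(segs, chr)
  expect_equal(nrow(j), 0)
})

test_that("junction reads from a circularized strain agree on (L, R)", {
  g <- small_genome(seed = 52)
  dl <- 2000; dr <- 3000
  n <- g$replicons$chr$length
  mut <- derive_strain(g, strain_spec(
    circularize = list(name = "chr", left_del = dl, right_del = dr)))
  sim <- simulate_reads(mut, mean_depth = 50, read_len = 150, seed = 53,
                        sub_error = 0)
  segs <- map_reads(g, sim$reads)
  j <- find_junctions(segs[segs$replicon == "chr", ], g$replicons$chr)
  expect_gte(nrow(j), 5)
  expect_equal(unique(j$L), dl + 1)
  expect_equal(unique(j$R), n - dr)
})

test_that("call_topology reproduces the worked junction arithmetic", {
  n <- 6748580
  ev <- data.frame(query_id = c("read1", "read2"), R = 6632666, L = 98994,
                   right_anchor_len = 100, left_anchor_len = 100,
                   junction_gap = 0)
  bl <- structure(list(replicon = "chr", end = "left", position = 98994,
                       support_depth = 100), class = "terminal_boundary")
  br <- structure(list(replicon = "chr", end = "right", position = 6632666,
                       support_depth = 100), class = "terminal_boundary")
  call <- call_topology(bl, br, ev, n)
  expect_identical(call$status, "circularized")
  expect_equal(call$left_deletion, 98993)
  expect_equal(call$right_deletion, 115914)
  expect_equal(unname(deletion_sizes_kb(call)), c(99, 116))
})

test_that("coverage-only deletions give terminal_deletion_only, not a circle", {
  n <- 6748580
  bl <- structure(list(replicon = "chr", end = "left", position = 120225,
                       support_depth = 80), class = "terminal_boundary")
  br <- structure(list(replicon = "chr", end = "right", position = 6660447,
                       support_depth = 80), class = "terminal_boundary")
  call <- call_topology(bl, br, NULL, n)
  expect_identical(call$status, "terminal_deletion_only")
  expect_equal(call$left_deletion, 120224)
  expect_equal(call$right_deletion, 88133)
  expect_equal(unname(deletion_sizes_kb(call)), c(120, 88))
})

test_that("intact boundaries with no junctions give an intact call", {
  bl <- structure(list(replicon = "chr", end = "left", position = 1,
                       support_depth = 50), class = "terminal_boundary")
  br <- structure(list(replicon = "chr", end = "right", position = 10000,
                       support_depth = 50), class = "terminal_boundary")
  call <- call_topology(bl, br, NULL, 10000)
  expect_identical(call$status, "intact")
  expect_equal(unname(deletion_sizes_kb(call)), c(0, 0))
})

test_that("raising min_evidence never upgrades a call to circularized", {
  n <- 100000
  bl <- structure(list(replicon = "chr", end = "left", position = 2001,
                       support_depth = 30), class = "terminal_boundary")
  br <- structure(list(replicon = "chr", end = "right", position = 97000,
                       support_depth = 30), class = "terminal_boundary")
  ev <- data.frame(query_id = "r1", R = 97000, L = 2001,
                   right_anchor_len = 80, left_anchor_len = 70,
                   junction_gap = 0)
  statuses <- vapply(1:5, function(me) {
    call_topology(bl, br, ev, n, min_evidence = me)$status
  }, character(1))
  expect_identical(statuses[1], "circularized")
  # one short-anchored read is insufficient beyond min_evidence = 1
  expect_true(all(statuses[2:5] == "terminal_deletion_only"))

  # ...but a single long-anchored contig is decisive on its own
  contig <- data.frame(query_id = "contig", R = 97000, L = 2001,
                       right_anchor_len = 5000, left_anchor_len = 7000,
                       junction_gap = 0)
  expect_identical(call_topology(bl, br, contig, n,
                                 min_evidence = 2)$status, "circularized")
})

test_that("conflicting junction clusters raise an ambiguity error", {
  n <- 100000
  bl <- structure(list(replicon = "chr", end = "left", position = 2001,
                       support_depth = 30), class = "terminal_boundary")
  br <- structure(list(replicon = "chr", end = "right", position = 97000,
                       support_depth = 30), class = "terminal_boundary")
  ev <- data.frame(query_id = c("a", "b", "c", "d"),
                   R = c(97000, 97000, 90000, 90000),
                   L = c(2001, 2001, 8000, 8000),
                   right_anchor_len = 100, left_anchor_len = 100,
                   junction_gap = 0)
  expect_error(call_topology(bl, br, ev, n), "conflicting")
})

test_that("junctions disagreeing with boundaries fall back with a warning", {
  n <- 100000
  bl <- structure(list(replicon = "chr", end = "left", position = 2001,
                       support_depth = 30), class = "terminal_boundary")
  br <- structure(list(replicon = "chr", end = "right", position = 97000,
                       support_depth = 30), class = "terminal_boundary")
  ev <- data.frame(query_id = c("a", "b"), R = 50000, L = 30000,
                   right_anchor_len = 100, left_anchor_len = 100,
                   junction_gap = 0)
  call <- call_topology(bl, br, ev, n)
  expect_identical(call$status, "terminal_deletion_only")
  expect_match(call$warnings, "disagrees")
})

test_that("kb rounding is half away from zero", {
  mk <- function(ld, rd) {
    circularization_call("chr", ld + 1, 1e6 - rd, 1e6,
                         status = "terminal_deletion_only")
  }
  expect_equal(unname(deletion_sizes_kb(mk(98993, 115914))), c(99, 116))
  expect_equal(unname(deletion_sizes_kb(mk(120224, 88133))), c(120, 88))
  expect_equal(unname(deletion_sizes_kb(mk(0, 0))), c(0, 0))
  expect_equal(unname(deletion_sizes_kb(mk(500, 499))), c(1, 0))
})

test_that("genome loss fraction sums lost replicons and deletions", {
  g <- genome(list(
    generate_replicon(6748580, seed = 60, name = "chromosome"),
    generate_replicon(1794824, seed = 61, name = "megaplasmid"),
    generate_replicon(149702, seed = 62, name = "plasmid2"),
    generate_replicon(11696, seed = 63, name = "plasmid1")
  ), chromosome_name = "chromosome")
  call <- circularization_call("chromosome", 98994, 6632666, 6748580,
                               status = "terminal_deletion_only")
  pct <- genome_loss_fraction(g, "megaplasmid", call)
  # independent arithmetic: (1794824 + 98993 + 115914) / 8704802 * 100
  expect_equal(pct, 100 * (1794824 + 98993 + 115914) / 8704802)
  expect_equal(round(pct, 2), 23.09)
  expect_gte(pct, 20)

  expect_equal(genome_loss_fraction(g), 0)
  g1 <- genome(list(generate_replicon(5000, seed = 64, name = "only")))
  expect_equal(genome_loss_fraction(g1, "only"), 100)
  expect_error(genome_loss_fraction(g, "nope"), "unknown")
})

test_that("the called (L, R) reconstructs the mutant sequence exactly", {
  for (s in c(70, 71, 72)) {
    g <- small_genome(seed = s)
    dl <- 1500 + s; dr <- 2500 + s
    mut <- derive_strain(g, strain_spec(
      circularize = list(name = "chr", left_del = dl, right_del = dr)))
    sim <- simulate_reads(mut, mean_depth = 30, read_len = 150, seed = s + 100)
    segs <- map_reads(g, sim$reads)
    chr_segs <- segs[segs$replicon == "chr", ]
    prof <- compute_coverage(chr_segs, g$replicons$chr)
    bl <- detect_boundary(prof, "left")
    br <- detect_boundary(prof, "right")
    j <- find_junctions(chr_segs, g$replicons$chr)
    call <- call_topology(bl, br, j, g$replicons$chr$length)
    expect_identical(call$status, "circularized")
    rebuilt <- substr(g$replicons$chr$sequence, call$L, call$R)
    expect_identical(rebuilt, mut$replicons$chr$sequence)
  }
})
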