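# Graph builders for hand-made genes (0-based half-open coordinates).
graph_from_transcripts <- function(tx_list, strand = "+", gene_id = "g",
                                   chrom = "chr1") {
  ex <- do.call(rbind, lapply(seq_along(tx_list), function(i) {
    m <- tx_list[[i]]
    data.frame(chrom = chrom, start = m[, 1L], end = m[, 2L], strand = strand,
               gene_id = gene_id, transcript_id = sprintf("%s.t%d", gene_id, i),
               stringsAsFactors = FALSE)
  }))
  rasekit:::build_splice_graph(ex)
}

tx <- function(...) matrix(c(...), ncol = 2L, byrow = TRUE)

test_that("exon skipping: inclusion junctions are the model path", {
  g <- graph_from_transcripts(list(
    tx(0, 100, 200, 300, 400, 500),   # e1, e2, e3
    tx(0, 100, 400, 500)))            # e1, e3
  ev <- enumerate_known_events(g)
  expect_identical(ev$event_type, "ES")
  expect_identical(ev$alt_start, 200L)
  expect_identical(ev$alt_end, 300L)
  expect_setequal(ev$model_junctions[[1]],
                  c("chr1:100:200:+", "chr1:300:400:+"))
  expect_identical(ev$alt_junctions[[1]], "chr1:100:400:+")
})

test_that("a multi-exon cassette is typed CE, not ES", {
  g <- graph_from_transcripts(list(
    tx(0, 100, 200, 300, 400, 500, 600, 700),
    tx(0, 100, 600, 700)))
  ev <- enumerate_known_events(g)
  expect_identical(ev$event_type, "CE")
  expect_identical(ev$alt_start, 200L)
  expect_identical(ev$alt_end, 500L)
  expect_length(ev$model_junctions[[1]], 3L)
})

test_that("alternative donor/acceptor typing is strand-aware", {
  donor_shift <- list(tx(0, 160, 300, 400), tx(0, 100, 300, 400))
  ev_plus <- enumerate_known_events(graph_from_transcripts(donor_shift, "+"))
  expect_identical(ev_plus$event_type, "A5SS")
  # model is the proximal (longer-exon) junction, alt the distal one
  expect_identical(ev_plus$model_junctions[[1]], "chr1:160:300:+")
  expect_identical(ev_plus$alt_junctions[[1]], "chr1:100:300:+")
  ev_minus <- enumerate_known_events(graph_from_transcripts(donor_shift, "-"))
  expect_identical(ev_minus$event_type, "A3SS")

  acc_shift <- list(tx(0, 100, 240, 400), tx(0, 100, 300, 400))
  expect_identical(
    enumerate_known_events(graph_from_transcripts(acc_shift, "+"))$event_type,
    "A3SS")
  expect_identical(
    enumerate_known_events(graph_from_transcripts(acc_shift, "-"))$event_type,
    "A5SS")
})

test_that("mutually exclusive exons require zero co-occurrence", {
  g <- graph_from_transcripts(list(
    tx(0, 100, 200, 300, 600, 700),    # e1, A, e4
    tx(0, 100, 400, 500, 600, 700)))   # e1, B, e4
  ev <- enumerate_known_events(g)
  expect_identical(ev$event_type, "MXE")
  expect_setequal(ev$model_junctions[[1]],
                  c("chr1:100:200:+", "chr1:300:600:+"))
  expect_setequal(ev$alt_junctions[[1]],
                  c("chr1:100:400:+", "chr1:500:600:+"))
  # a third transcript carrying both exons kills the MXE
  g2 <- graph_from_transcripts(list(
    tx(0, 100, 200, 300, 600, 700),
    tx(0, 100, 400, 500, 600, 700),
    tx(0, 100, 200, 300, 400, 500, 600, 700)))
  expect_false("MXE" %in% enumerate_known_events(g2)$event_type)
})

test_that("alternative first/last exon variants are recognized structurally", {
  first <- list(tx(0, 100, 400, 500, 600, 700),
                tx(200, 300, 400, 500, 600, 700))
  ev <- enumerate_known_events(graph_from_transcripts(first, "+"))
  expect_identical(ev$event_type, "5pMXE")
  # the same structure on '-' has the alternatives at the transcript 3' end
  ev_m <- enumerate_known_events(graph_from_transcripts(first, "-"))
  expect_identical(ev_m$event_type, "3pMXE")

  last <- list(tx(0, 100, 200, 300, 400, 500),
               tx(0, 100, 200, 300, 600, 700))
  expect_identical(
    enumerate_known_events(graph_from_transcripts(last, "+"))$event_type,
    "3pMXE")
  expect_identical(
    enumerate_known_events(graph_from_transcripts(last, "-"))$event_type,
    "5pMXE")
})

test_that("intron retention needs an exon containing the intron", {
  g <- graph_from_transcripts(list(tx(0, 100, 200, 300), tx(0, 300)))
  ev <- enumerate_known_events(g)
  expect_identical(ev$event_type, "IR")
  expect_identical(ev$alt_start, 100L)
  expect_identical(ev$alt_end, 200L)
  expect_length(ev$alt_junctions[[1]], 0L)
  expect_identical(ev$model_junctions[[1]], "chr1:100:200:+")
})

test_that("single-transcript genes give an empty event table, no error", {
  g <- graph_from_transcripts(list(tx(0, 100, 200, 300)))
  expect_identical(nrow(enumerate_known_events(g)), 0L)
})

test_that("enumeration is invariant to transcript order and never
           double-counts a junction on both sides", {
  tx_set <- list(tx(0, 100, 200, 300, 400, 500),
                 tx(0, 100, 400, 500),
                 tx(0, 160, 400, 500))
  perms <- list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))
  evs <- lapply(perms, function(p) {
    enumerate_known_events(graph_from_transcripts(tx_set[p]))
  })
  for (i in 2:3) {
    expect_identical(evs[[1]]$event_id, evs[[i]]$event_id)
    expect_identical(evs[[1]]$model_junctions, evs[[i]]$model_junctions)
  }
  for (i in seq_len(nrow(evs[[1]]))) {
    expect_length(intersect(evs[[1]]$model_junctions[[i]],
                            evs[[1]]$alt_junctions[[i]]), 0L)
  }
})

test_that("toy annotation recovers one planted instance of every type", {
  ann <- make_toy_annotation(one_of_each_mix(), seed = 3)
  ev <- enumerate_all_known_events(ann$graphs)
  expect_identical(nrow(ev), 8L)
  expect_setequal(ev$event_type, all_event_types)
  expect_setequal(ev$event_id, ann$truth$event_id)
  # exact coordinates and junction sets, per planted truth
  m <- match(ann$truth$event_id, ev$event_id)
  expect_identical(ev$alt_start[m], ann$truth$alt_start)
  expect_identical(ev$alt_end[m], ann$truth$alt_end)
  for (i in seq_len(nrow(ann$truth))) {
    expect_setequal(ev$model_junctions[[m[i]]], ann$truth$model_junctions[[i]])
    expect_setequal(ev$alt_junctions[[m[i]]], ann$truth$alt_junctions[[i]])
  }
})

test_that("novel junctions are typed against their annotated anchors", {
  g <- graph_from_transcripts(list(tx(0, 100, 300, 400, 600, 700),
                                   tx(0, 100, 600, 700)))
  # donor shifted -30 nt from annotated (100,300), shared acceptor -> A5SS
  ev1 <- discover_novel_events(g, junction_evidence("s", c(`chr1:70:300:+` = 10L)))
  expect_identical(ev1$event_type, "A5SS")
  expect_false(ev1$known)
  expect_identical(ev1$alt_junctions[[1]], "chr1:70:300:+")
  expect_identical(ev1$model_junctions[[1]], "chr1:100:300:+")
  # orphan: no annotated anchor -> reported separately, no event
  ev2 <- discover_novel_events(g, junction_evidence("s", c(`chr1:150:250:+` = 10L)))
  expect_identical(nrow(ev2), 0L)
  expect_identical(attr(ev2, "orphans"), "chr1:150:250:+")
  # below min_reads support -> nothing
  ev3 <- discover_novel_events(g, junction_evidence("s", c(`chr1:70:300:+` = 1L)),
                               min_reads = 2)
  expect_identical(nrow(ev3), 0L)
})

test_that("three planted novel junction classes are all recovered", {
  g <- graph_from_transcripts(list(
    tx(0, 100, 300, 400, 600, 700, 900, 1000),
    tx(0, 100, 900, 1000)))
  ev <- discover_novel_events(g, junction_evidence("s", c(
    `chr1:70:300:+` = 5L,    # donor shift -> novel A5SS
    `chr1:100:350:+` = 5L,   # acceptor shift -> novel A3SS
    `chr1:100:600:+` = 5L))) # unannotated exon-edge combination -> novel ES
  expect_setequal(ev$event_type, c("A5SS", "A3SS", "ES"))
  expect_true(all(!ev$known))
})

test_that("event read counting sums junction evidence by side", {
  g <- graph_from_transcripts(list(
    tx(0, 100, 200, 300, 400, 500), tx(0, 100, 400, 500)))
  ev <- enumerate_known_events(g)
  evd <- junction_evidence("s", c(`chr1:100:200:+` = 30L,
                                  `chr1:300:400:+` = 50L,
                                  `chr1:100:400:+` = 20L))
  cnt <- count_event_reads(ev, evd)
  expect_identical(cnt$alt_reads, 20L)
  expect_identical(cnt$model_reads, 80L)
  # no observed junctions -> zeros
  cnt0 <- count_event_reads(ev, junction_evidence("s2"))
  expect_identical(cnt0$alt_reads, 0L)
  expect_identical(cnt0$model_reads, 0L)
})

test_that("IR events count the conservative boundary minimum", {
  g <- graph_from_transcripts(list(tx(0, 100, 200, 300), tx(0, 300)))
  ev <- enumerate_known_events(g)
  evd <- junction_evidence("s", c(`chr1:100:200:+` = 40L),
                           boundary_counts = data.frame(
                             junction = "chr1:100:200:+",
                             left = 12L, right = 9L))
  cnt <- count_event_reads(ev, evd)
  expect_identical(cnt$alt_reads, 9L)
  expect_identical(cnt$model_reads, 40L)
})

test_that("event tables round-trip through the TSV writer", {
  ann <- make_toy_annotation(one_of_each_mix(), seed = 2)
  ev <- enumerate_all_known_events(ann$graphs)
  path <- tempfile(fileext = ".tsv")
  write_event_table(ev, path)
  back <- read_event_table(path)
  expect_identical(back$event_id, ev$event_id)
  expect_identical(lapply(back$model_junctions, identity),
                   lapply(ev$model_junctions, identity))
})
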