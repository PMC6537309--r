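test_that("toy annotations are deterministic and validated", {
  expect_error(make_toy_annotation(c(XX = 1L)), "unknown event type")
  expect_error(make_toy_annotation(c(ES = -1L)), ">= 0")
  g1 <- tempfile(fileext = ".gtf"); g2 <- tempfile(fileext = ".gtf")
  make_toy_annotation(c(ES = 1L, MXE = 2L), seed = 4, gtf_path = g1)
  make_toy_annotation(c(ES = 1L, MXE = 2L), seed = 4, gtf_path = g2)
  expect_identical(readLines(g1), readLines(g2))
  ann <- make_toy_annotation(c(ES = 1L))
  expect_length(ann$graphs, 1L)
  expect_identical(ann$truth$event_type, "ES")
})

test_that("gene blocks do not overlap across the toy chromosome", {
  ann <- make_toy_annotation(one_of_each_mix(), seed = 1)
  spans <- t(vapply(ann$graphs, function(g) {
    c(min(g$exons$start), max(g$exons$end))
  }, numeric(2)))
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  expect_true(all(spans[-1, 1] >= spans[-nrow(spans), 2]))
})

test_that("splicing truth plants the declared effect size exactly", {
  tr <- make_splicing_truth(sprintf("e%d", 1:500), n_regulated = 200,
                            effect_size = 0.3, seed = 2)
  expect_identical(sum(tr$planted_rase), 200L)
  expect_equal(abs(tr$psi_a - tr$psi_b)[tr$planted_rase], rep(0.3, 200),
               tolerance = 1e-12)
  expect_equal(tr$psi_a[!tr$planted_rase], tr$psi_b[!tr$planted_rase])
  expect_true(all(tr$psi_a >= 0 & tr$psi_a <= 1))
  expect_true(all(tr$psi_b >= 0 & tr$psi_b <= 1))
  # direction balance comes from seeded coin flips, not list order
  prop_up <- mean(tr$psi_b[tr$planted_rase] > tr$psi_a[tr$planted_rase])
  expect_gt(prop_up, 0.3); expect_lt(prop_up, 0.7)
})

test_that("event count simulation respects the binomial inclusion model", {
  tr <- data.frame(event_id = c("zero", "half", "one"),
                   psi_a = c(0, 0.5, 1), psi_b = c(0, 0.5, 1),
                   planted_rase = FALSE)
  cnt <- simulate_event_counts(tr, depth_per_event = 1e6,
                               n_samples_per_condition = 1, seed = 3)
  z <- cnt[cnt$event_id == "zero", ]
  expect_true(all(z$alt_reads == 0))
  o <- cnt[cnt$event_id == "one", ]
  expect_true(all(o$model_reads == 0))
  h <- cnt[cnt$event_id == "half", ]
  expect_true(all(abs(h$alt_reads / 1e6 - 0.5) < 0.002))
  # seed determinism
  cnt2 <- simulate_event_counts(tr, 1e6, 1, seed = 3)
  expect_identical(cnt, cnt2)
  expect_error(simulate_event_counts(data.frame(event_id = "x", psi_a = 1.2,
                                                psi_b = 0.5), 10),
               "psi")
})

test_that("beta-binomial dispersion widens replicate spread", {
  tr <- data.frame(event_id = sprintf("e%d", 1:200),
                   psi_a = 0.5, psi_b = 0.5, planted_rase = FALSE)
  tight <- simulate_event_counts(tr, 100, 20, dispersion = 0, seed = 6)
  wide <- simulate_event_counts(tr, 100, 20, dispersion = 0.2, seed = 6)
  v <- function(x) mean(tapply(x$alt_reads, x$event_id, var))
  expect_gt(v(wide), 2 * v(tight))
})

test_that("junction evidence distributes event counts conservatively", {
  ann <- make_toy_annotation(one_of_each_mix(), seed = 8)
  tr <- make_splicing_truth(ann$truth$event_id, n_regulated = 0, seed = 8)
  jc <- simulate_junction_counts(ann, tr, depth_per_event = 97,
                                 n_samples_per_condition = 2, seed = 8,
                                 junction_fraction = 0.25)
  ev1 <- jc$evidence[[1]]
  # per event: alt + model recovered by the counting path equals depth
  cnt <- count_event_reads(ann$truth, ev1)
  expect_true(all(cnt$alt_reads + cnt$model_reads == 97L))
  expect_equal(junction_read_fraction(ev1), 0.25, tolerance = 0.01)
  # per-sample totals match the per_sample table
  ps <- jc$per_sample[jc$per_sample$sample_id == ev1$sample_id, ]
  m <- match(cnt$event_id, ps$event_id)
  expect_identical(cnt$alt_reads, ps$alt_reads[m])
})

test_that("expression simulation hits planted means and fold changes", {
  truth <- make_expression_truth(sprintf("g%d", 1:50), n_deg = 10,
                                 fold_change = 2, seed = 12)
  exact <- simulate_expression(truth, n_samples_per_condition = 2,
                               noise_sd_log2 = 0, seed = 12)
  expect_equal(unname(exact$expr[, "a1"]), truth$mean_a)
  expect_equal(unname(exact$expr[, "b2"]), truth$mean_b)
  # planted FC converges with many replicates
  big <- simulate_expression(truth, n_samples_per_condition = 200,
                             noise_sd_log2 = 0.3, seed = 12)
  sheet <- big$sample_sheet
  fc <- fold_changes(big$expr, sheet$sample_id[sheet$condition == "a"],
                     sheet$sample_id[sheet$condition == "b"], pseudocount = 0)
  planted <- truth$planted_deg
  expect_equal(mean(fc$fold_change[!planted]), 1, tolerance = 0.05)
  ratio <- fc$fold_change[planted] / (truth$mean_b / truth$mean_a)[planted]
  expect_true(all(abs(log2(ratio)) < 0.25))
  # determinism
  again <- simulate_expression(truth, 200, 0.3, seed = 12)
  expect_identical(big$expr, again$expr)
})

test_that("emitted SAM round-trips through extraction bit-exactly", {
  ann <- make_toy_annotation(one_of_each_mix(), seed = 13)
  tr <- make_splicing_truth(ann$truth$event_id, n_regulated = 2, seed = 13)
  jc <- simulate_junction_counts(ann, tr, depth_per_event = 60,
                                 n_samples_per_condition = 1, seed = 13)
  ev0 <- jc$evidence[[1]]
  sam <- tempfile(fileext = ".sam")
  write_evidence_sam(ev0, sam)
  ev1 <- extract_junctions_from_sam(sam, ev0$sample_id, graphs = ann$graphs)
  expect_identical(ev1$counts[names(ev0$counts)], ev0$counts)
  expect_identical(ev1$total_mapped_fragments, ev0$total_mapped_fragments)
  b0 <- ev0$boundary_counts
  m <- match(b0$junction, ev1$boundary_counts$junction)
  expect_identical(ev1$boundary_counts$left[m], b0$left)
  expect_identical(ev1$boundary_counts$right[m], b0$right)
})
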