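test_that("AS ratio follows alt / (alt + model)", {
  expect_equal(as_ratio(25, 75), 0.25)
  expect_equal(as_ratio(0, 50), 0)
  expect_equal(as_ratio(50, 0), 1)
  expect_true(is.na(as_ratio(0, 0)))
  expect_error(as_ratio(-1, 5), "non-negative")
})

test_that("Fisher p matches hand-derived exact values", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  # [[10,0],[0,10]]: the two extreme tables out of C(20,10)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / 184756, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(20, 80, 50, 50),
               oracle_fisher2x2(20, 80, 50, 50), tolerance = 1e-12)
  # degenerate margins
  expect_equal(fisher_exact_2x2(0, 0, 3, 4), 1)
  expect_equal(fisher_exact_2x2(0, 5, 0, 7), 1)
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("Fisher p is symmetric under row and column swaps", {
  set.seed(42)
  for (i in 1:50) {
    t4 <- rpois(4, 8)
    p <- fisher_exact_2x2(t4[1], t4[2], t4[3], t4[4])
    expect_equal(fisher_exact_2x2(t4[3], t4[4], t4[1], t4[2]), p)
    expect_equal(fisher_exact_2x2(t4[2], t4[1], t4[4], t4[3]), p)
  }
})

test_that("Fisher p agrees with stats::fisher.test two-sided", {
  set.seed(7)
  for (i in 1:100) {
    t4 <- rpois(4, 15)
    if (sum(t4) == 0) next
    expect_equal(fisher_exact_2x2(t4[1], t4[2], t4[3], t4[4]),
                 fisher.test(matrix(t4, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("pooling sums replicate counts within conditions", {
  per_sample <- data.frame(
    event_id = "e1",
    sample_id = c("a1", "a2", "b1"),
    condition = c("a", "a", "b"),
    alt_reads = c(10L, 6L, 9L),
    model_reads = c(30L, 34L, 31L))
  ec <- pool_event_counts(per_sample, "a", "b")
  expect_identical(ec$alt_a, 16L)
  expect_identical(ec$model_a, 64L)
  expect_identical(ec$alt_b, 9L)
  # single-sample condition pools to itself
  expect_identical(ec$model_b, 31L)
  expect_error(pool_event_counts(per_sample[1:2, ], "a", "b"), "condition")
})

test_that("pooled condition totals equal the generator's marginals", {
  ann <- make_toy_annotation(one_of_each_mix(), seed = 5)
  truth <- make_splicing_truth(ann$truth$event_id, n_regulated = 3, seed = 5)
  jc <- simulate_junction_counts(ann, truth, depth_per_event = 80,
                                 n_samples_per_condition = 3, seed = 5)
  ec <- pool_condition(ann$truth, jc$evidence, jc$sample_sheet, "a", "b")
  ps <- jc$per_sample
  for (i in seq_len(nrow(ec))) {
    id <- ec$event_id[i]
    expect_identical(ec$alt_a[i],
                     sum(ps$alt_reads[ps$event_id == id & ps$condition == "a"]))
    expect_identical(ec$model_b[i],
                     sum(ps$model_reads[ps$event_id == id & ps$condition == "b"]))
  }
})

test_that("RASE calling applies both thresholds strictly", {
  ec <- data.frame(event_id = c("e1", "e2", "e3"),
                   alt_a = c(20L, 20L, 30L), model_a = c(80L, 80L, 70L),
                   alt_b = c(50L, 20L, 45L), model_b = c(50L, 80L, 55L))
  r <- call_rases(ec)
  # e1: ratios 0.2 vs 0.5
  expect_equal(r$rase_ratio[1], 0.3)
  expect_equal(r$p_value[1], oracle_fisher2x2(20, 80, 50, 50), tolerance = 1e-12)
  expect_true(r$is_rase[1])
  expect_identical(r$direction[1], "up")
  # e2: identical counts
  expect_equal(r$rase_ratio[2], 0)
  expect_equal(r$p_value[2], 1)
  expect_false(r$is_rase[2])
  # e3: delta 0.15 < 0.2 stays uncalled regardless of p
  expect_equal(r$rase_ratio[3], 0.15)
  expect_false(r$is_rase[3])
})

test_that("a ratio change exactly at the threshold is not called", {
  # strict inequality: delta == 0.2 fails the > 0.2 filter even at p ~ 0
  ec <- data.frame(event_id = "e", alt_a = 0L, model_a = 1000L,
                   alt_b = 200L, model_b = 800L)
  r <- call_rases(ec)
  expect_equal(r$rase_ratio, 0.2)
  expect_true(r$p_value < 0.05)
  expect_false(r$is_rase)
})

test_that("untestable events are flagged, not dropped", {
  ec <- data.frame(event_id = c("e1", "e2"),
                   alt_a = c(0L, 10L), model_a = c(0L, 90L),
                   alt_b = c(5L, 40L), model_b = c(5L, 60L))
  r <- call_rases(ec)
  expect_identical(nrow(r), 2L)
  expect_false(r$testable[1])
  expect_true(is.na(r$p_value[1]))
  expect_false(r$is_rase[1])
  expect_true(r$testable[2])
})

test_that("calling is monotone in the ratio difference at fixed depth", {
  depth <- 200L
  alt_b <- seq(40L, 160L, by = 20L)
  ec <- data.frame(event_id = sprintf("e%d", seq_along(alt_b)),
                   alt_a = 40L, model_a = depth - 40L,
                   alt_b = alt_b, model_b = depth - alt_b)
  r <- call_rases(ec)
  # p decreases and is_rase never reverts to FALSE as |delta| grows
  expect_true(all(diff(r$p_value) <= 1e-12))
  expect_true(all(diff(as.integer(r$is_rase)) >= 0L))
})

test_that("per-type up/down tallies join records to events", {
  events <- data.frame(event_id = c("e1", "e2", "e3"),
                       gene_id = "g", event_type = c("ES", "ES", "A5SS"),
                       known = TRUE, chrom = "chr1", strand = "+",
                       alt_start = 1L, alt_end = 2L)
  records <- data.frame(event_id = c("e1", "e2", "e3"),
                        is_rase = c(TRUE, TRUE, TRUE),
                        direction = c("up", "up", "down"))
  tc <- classify_rase_types(records, events)
  expect_identical(tc$n_up[tc$event_type == "ES"], 2L)
  expect_identical(tc$n_down[tc$event_type == "A5SS"], 1L)
  expect_identical(tc$n_down[tc$event_type == "ES"], 0L)
  records$event_id[1] <- "nope"
  expect_error(classify_rase_types(records, events), "unknown event_id")
  empty <- classify_rase_types(records[0, ], events)
  expect_identical(nrow(empty), 0L)
})

test_that("planted per-type regulation tallies match the truth", {
  mix <- stats::setNames(rep(2L, 4), c("ES", "A5SS", "A3SS", "MXE"))
  ann <- make_toy_annotation(mix, seed = 9)
  truth <- make_splicing_truth(ann$truth$event_id, n_regulated = 4,
                               effect_size = 0.4, seed = 9)
  jc <- simulate_junction_counts(ann, truth, depth_per_event = 400,
                                 n_samples_per_condition = 2, seed = 9)
  ec <- pool_condition(ann$truth, jc$evidence, jc$sample_sheet, "a", "b")
  r <- call_rases(ec)
  expect_setequal(r$event_id[r$is_rase],
                  truth$event_id[truth$planted_rase])
  tc <- classify_rase_types(r, ann$truth)
  planted_dir <- ifelse(truth$psi_b > truth$psi_a, "up", "down")[truth$planted_rase]
  planted_type <- ann$truth$event_type[match(truth$event_id[truth$planted_rase],
                                             ann$truth$event_id)]
  for (ty in unique(planted_type)) {
    expect_identical(tc$n_up[tc$event_type == ty],
                     sum(planted_type == ty & planted_dir == "up"))
    expect_identical(tc$n_down[tc$event_type == ty],
                     sum(planted_type == ty & planted_dir == "down"))
  }
})
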