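# Differential splicing between two conditions: per-event AS ratios,
# Fisher's exact test on pooled alternative/model junction reads, and
# regulated-event (RASE) calling with a ratio-change filter.

#' Alternative-splicing ratio of one event
#'
#' `alt / (alt + model)` — the fraction of junction reads supporting the
#' alternative path, a junction-read analogue of percent-spliced-in.
#'
#' @param alt_reads,model_reads Non-negative read counts (vectorized).
#' @return Numeric in `[0, 1]`; `NA` where `alt + model == 0` (the event
#'   is untestable, never silently zero).
#' @export
#' @examples
#' as_ratio(25, 75)  # 0.25
as_ratio <- function(alt_reads, model_reads) {
  if (any(alt_reads < 0, na.rm = TRUE) || any(model_reads < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative")
  }
  total <- alt_reads + model_reads
  ifelse(total > 0, alt_reads / total, NA_real_)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p by hypergeometric enumeration: with the table
#' margins fixed, sum the probabilities of all tables whose probability
#' does not exceed that of the observed table (ties resolved within a
#' relative tolerance of 1e-7). The table is
#' `rbind(c(a, b), c(c, d))`; here rows are conditions and columns
#' alternative/model junction reads. All arguments are vectorized.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return Two-sided p-value(s) in `[0, 1]`; degenerate tables (an empty
#'   row or column margin) give 1.
#' @export
#' @examples
#' fisher_exact_2x2(10, 0, 0, 10)
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(is.na(c(a, b, c, d))) || any(c(a, b, c, d) < 0)) {
    stop("all cell counts must be non-negative and non-missing")
  }
  vapply(seq_len(n), function(i) {
    .fisher2x2_scalar(a[i], b[i], c[i], d[i])
  }, numeric(1))
}

.fisher2x2_scalar <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c; n2 <- b + d
  if (m1 + m2 == 0) stop("empty 2x2 table")
  if (m1 == 0 || m2 == 0 || n1 == 0 || n2 == 0) return(1.0)
  lo <- max(0, n1 - m2); hi <- min(m1, n1)
  probs <- dhyper(lo:hi, m1, m2, n1)
  p_obs <- probs[a - lo + 1L]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Pool per-sample event counts within each condition
#'
#' Sums alternative and model junction reads across the member samples of
#' each condition, yielding the 2x2 table tested per event. Per-sample
#' counts are retained for heterogeneity QC.
#'
#' @param events An event table (see [enumerate_known_events()]).
#' @param evidence_list List of [junction_evidence()] objects, one per
#'   sample.
#' @param sample_sheet data.frame with columns `sample_id`, `condition`.
#' @param condition_a,condition_b The two condition labels; default the
#'   first two in `sample_sheet` order. Direction "up" later means a
#'   higher AS ratio in `condition_b`.
#' @return data.frame with columns `event_id`, `alt_a`, `model_a`,
#'   `alt_b`, `model_b`; the long per-sample table is attached as
#'   attribute `"per_sample"`.
#' @export
pool_condition <- function(events, evidence_list, sample_sheet,
                           condition_a = NULL, condition_b = NULL) {
  stopifnot(all(c("sample_id", "condition") %in% names(sample_sheet)))
  conds <- unique(sample_sheet$condition)
  if (is.null(condition_a)) condition_a <- conds[1L]
  if (is.null(condition_b)) condition_b <- setdiff(conds, condition_a)[1L]
  for (cc in c(condition_a, condition_b)) {
    if (!any(sample_sheet$condition == cc)) {
      stop("condition '", cc, "' has no samples")
    }
  }
  ids <- vapply(evidence_list, `[[`, character(1), "sample_id")
  per_sample <- do.call(rbind, lapply(seq_along(evidence_list), function(i) {
    cnt <- count_event_reads(events, evidence_list[[i]])
    cnt$sample_id <- ids[i]
    cnt$condition <- sample_sheet$condition[match(ids[i], sample_sheet$sample_id)]
    cnt
  }))
  per_sample <- per_sample[!is.na(per_sample$condition), , drop = FALSE]
  pool_event_counts(per_sample, condition_a, condition_b,
                    event_order = events$event_id)
}

#' @rdname pool_condition
#' @param per_sample Long data.frame with columns `event_id`, `sample_id`,
#'   `condition`, `alt_reads`, `model_reads`.
#' @param event_order Optional event_id vector fixing output row order.
#' @export
pool_event_counts <- function(per_sample, condition_a, condition_b,
                              event_order = NULL) {
  sub <- function(cond, col) {
    x <- per_sample[per_sample$condition == cond, , drop = FALSE]
    tapply(x[[col]], x$event_id, sum)
  }
  if (!any(per_sample$condition == condition_a) ||
      !any(per_sample$condition == condition_b)) {
    stop("both conditions must have at least one sample")
  }
  aa <- sub(condition_a, "alt_reads"); am <- sub(condition_a, "model_reads")
  ba <- sub(condition_b, "alt_reads"); bm <- sub(condition_b, "model_reads")
  ids <- if (is.null(event_order)) sort(unique(per_sample$event_id)) else event_order
  z <- function(v) ifelse(is.na(v), 0L, as.integer(v))
  out <- data.frame(event_id = ids,
                    alt_a = z(aa[ids]), model_a = z(am[ids]),
                    alt_b = z(ba[ids]), model_b = z(bm[ids]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "per_sample") <- per_sample
  attr(out, "conditions") <- c(a = condition_a, b = condition_b)
  out
}

#' Call regulated alternative splicing events (RASEs)
#'
#' For each event with junction reads in both conditions, computes the
#' per-condition AS ratios, their absolute change (the RASE ratio) and a
#' two-sided Fisher exact p on the pooled 2x2 table
#' `(alt_a, model_a; alt_b, model_b)`. An event is called regulated when
#' `p < p_threshold` and the ratio change exceeds `ratio_threshold`
#' (strict inequalities). Benjamini-Hochberg q-values over the testable
#' events are reported alongside but are not used for calling. Events
#' with zero total reads in either condition are flagged untestable and
#' kept in the output.
#'
#' @param event_counts data.frame from [pool_condition()] (columns
#'   `event_id`, `alt_a`, `model_a`, `alt_b`, `model_b`).
#' @param p_threshold Fisher p cutoff, default 0.05.
#' @param ratio_threshold Minimum absolute AS-ratio change, default 0.2.
#' @return data.frame with the input counts plus `ratio_a`, `ratio_b`,
#'   `rase_ratio`, `p_value`, `q_value`, `is_rase`, `direction`
#'   (`"up"`: higher AS ratio in condition b) and `testable`.
#' @export
call_rases <- function(event_counts, p_threshold = 0.05,
                       ratio_threshold = 0.2) {
  stopifnot(all(c("event_id", "alt_a", "model_a", "alt_b", "model_b") %in%
                  names(event_counts)))
  ec <- event_counts
  ec$ratio_a <- as_ratio(ec$alt_a, ec$model_a)
  ec$ratio_b <- as_ratio(ec$alt_b, ec$model_b)
  ec$testable <- !is.na(ec$ratio_a) & !is.na(ec$ratio_b)
  ec$rase_ratio <- abs(ec$ratio_b - ec$ratio_a)
  ec$p_value <- NA_real_
  if (any(ec$testable)) {
    ec$p_value[ec$testable] <- fisher_exact_2x2(
      ec$alt_a[ec$testable], ec$model_a[ec$testable],
      ec$alt_b[ec$testable], ec$model_b[ec$testable])
  }
  ec$q_value <- NA_real_
  ec$q_value[ec$testable] <- bh_fdr(ec$p_value[ec$testable])
  ec$is_rase <- ec$testable & !is.na(ec$p_value) &
    ec$p_value < p_threshold & ec$rase_ratio > ratio_threshold
  ec$direction <- ifelse(!ec$testable | ec$ratio_b == ec$ratio_a,
                         NA_character_,
                         ifelse(ec$ratio_b > ec$ratio_a, "up", "down"))
  ec
}

#' Tally regulated events by type and direction
#'
#' Joins RASE records to their events and counts, per event type, how
#' many called events go up or down (the per-type regulation bar plot).
#'
#' @param records Output of [call_rases()].
#' @param events The event table the records were computed from.
#' @return data.frame with columns `event_type`, `n_up`, `n_down`,
#'   one row per type observed among the called events.
#' @export
classify_rase_types <- function(records, events) {
  if (nrow(records) == 0L) {
    return(data.frame(event_type = character(), n_up = integer(),
                      n_down = integer(), stringsAsFactors = FALSE))
  }
  idx <- match(records$event_id, events$event_id)
  if (anyNA(idx)) {
    stop("unknown event_id in RASE records: ",
         records$event_id[which(is.na(idx))[1L]])
  }
  called <- records[records$is_rase, , drop = FALSE]
  if (nrow(called) == 0L) {
    return(data.frame(event_type = character(), n_up = integer(),
                      n_down = integer(), stringsAsFactors = FALSE))
  }
  type <- events$event_type[match(called$event_id, events$event_id)]
  tally <- function(dir) {
    tab <- table(type[called$direction == dir])
    setNames(as.integer(tab), names(tab))
  }
  up <- tally("up"); down <- tally("down")
  types <- sort(unique(type))
  data.frame(event_type = types,
             n_up = ifelse(is.na(up[types]), 0L, up[types]),
             n_down = ifelse(is.na(down[types]), 0L, down[types]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a RASE result table to TSV
#'
#' @param records Output of [call_rases()].
#' @param events Optional event table; when given, gene and type columns
#'   are joined in.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rase_table <- function(records, path, events = NULL) {
  out <- records
  if (!is.null(events)) {
    idx <- match(records$event_id, events$event_id)
    out$gene_id <- events$gene_id[idx]
    out$event_type <- events$event_type[idx]
    front <- c("event_id", "gene_id", "event_type")
    out <- out[, c(front, setdiff(names(out), front)), drop = FALSE]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
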