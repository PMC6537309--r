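# Expression-side companions: extreme-group selection by a driver gene,
# fold-change DEG filtering, sample correlation, and qPCR ddCt arithmetic.

#' Select the extreme high/low sample groups for a driver gene
#'
#' Returns the `k` samples with the highest and the `k` with the lowest
#' expression of a driver gene, the design used to contrast splicing
#' between driver-high and driver-low tumors. Ties are broken by sample
#' id in lexicographic order, so the split is deterministic.
#'
#' @param expr Named numeric vector: the driver gene's expression per
#'   sample (names are sample ids).
#' @param k Group size; `2 * k` must not exceed the number of samples.
#' @return List with character vectors `high` and `low` (each length `k`).
#' @export
select_extreme_groups <- function(expr, k) {
  if (is.null(names(expr)) || anyDuplicated(names(expr))) {
    stop("expr must be named by unique sample ids")
  }
  n <- length(expr)
  if (2 * k > n) stop("2 * k exceeds the number of samples (", n, ")")
  ord_hi <- order(-expr, names(expr))
  ord_lo <- order(expr, names(expr))
  list(high = names(expr)[ord_hi[seq_len(k)]],
       low = names(expr)[ord_lo[seq_len(k)]])
}

#' Fold changes between two sample groups of an FPKM matrix
#'
#' Mean FPKM per group with a pseudocount added to both means before the
#' ratio (avoids division by zero on unexpressed genes).
#'
#' @param expr genes x samples numeric matrix (FPKM).
#' @param group_a,group_b Sample id vectors (columns of `expr`);
#'   fold change is `mean_b / mean_a`, i.e. condition over control with
#'   `group_a` as control.
#' @param pseudocount Added to both group means; default 0.1 FPKM.
#' @return data.frame with `gene_id`, `mean_a`, `mean_b`, `fold_change`.
#' @export
fold_changes <- function(expr, group_a, group_b, pseudocount = 0.1) {
  stopifnot(all(group_a %in% colnames(expr)), all(group_b %in% colnames(expr)))
  ma <- rowMeans(expr[, group_a, drop = FALSE])
  mb <- rowMeans(expr[, group_b, drop = FALSE])
  data.frame(gene_id = rownames(expr), mean_a = ma, mean_b = mb,
             fold_change = (mb + pseudocount) / (ma + pseudocount),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Threshold-filter differential expression calls
#'
#' Applies the fold-change plus significance contract: a gene is called
#' `up` when `fold_change >= fc_up` and its (FDR-adjusted, when
#' `use_fdr`) p-value is below `alpha`; `down` symmetrically with
#' `fold_change <= fc_down`; otherwise `ns`. The per-gene p-values come
#' from any upstream test (see [binomial_deg_test()] for the built-in
#' count-based default); genes with a missing p-value are kept as `ns`
#' and flagged.
#'
#' @param deg data.frame with columns `gene_id`, `fold_change`,
#'   `p_value`.
#' @param fc_up,fc_down Fold-change cutoffs (e.g. 2 and 0.5, or 1.5 and
#'   2/3).
#' @param use_fdr Apply Benjamini-Hochberg across genes and threshold the
#'   adjusted value instead of the raw p.
#' @param alpha Significance cutoff (FDR < alpha when `use_fdr`,
#'   p < alpha otherwise).
#' @return The input with added `fdr`, `call` (`up`/`down`/`ns`) and
#'   `missing_p` columns; up/down totals in attribute `"n_updown"`.
#' @export
deg_filter <- function(deg, fc_up = 2, fc_down = 0.5, use_fdr = TRUE,
                       alpha = 0.05) {
  stopifnot(all(c("gene_id", "fold_change", "p_value") %in% names(deg)))
  if (any(deg$fold_change <= 0, na.rm = TRUE)) {
    stop("fold changes must be positive")
  }
  out <- deg
  out$fdr <- NA_real_
  ok <- !is.na(out$p_value)
  out$fdr[ok] <- bh_fdr(out$p_value[ok])
  crit <- if (use_fdr) out$fdr else out$p_value
  sig <- ok & crit < alpha
  out$call <- "ns"
  out$call[sig & out$fold_change >= fc_up] <- "up"
  out$call[sig & out$fold_change <= fc_down] <- "down"
  out$missing_p <- !ok
  attr(out, "n_updown") <- c(up = sum(out$call == "up"),
                             down = sum(out$call == "down"))
  out
}

#' Per-gene exact binomial test on pooled fragment counts
#'
#' Default significance engine for [deg_filter()]: for each gene, the
#' pooled count in condition b is tested against the library-size
#' expectation `total_b / (total_a + total_b)` with a two-sided exact
#' binomial test. Deliberately simple — no dispersion modelling — so the
#' thresholds, not the test, carry the filtering contract.
#'
#' @param counts_a,counts_b Named vectors of pooled fragment counts per
#'   gene in each condition (same gene set).
#' @return data.frame with `gene_id`, `p_value`.
#' @export
binomial_deg_test <- function(counts_a, counts_b) {
  stopifnot(setequal(names(counts_a), names(counts_b)))
  counts_b <- counts_b[names(counts_a)]
  ta <- sum(counts_a); tb <- sum(counts_b)
  prob <- tb / (ta + tb)
  p <- vapply(seq_along(counts_a), function(i) {
    n <- counts_a[i] + counts_b[i]
    if (n == 0) return(NA_real_)
    binom.test(counts_b[i], n, p = prob)$p.value
  }, numeric(1))
  data.frame(gene_id = names(counts_a), p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pearson correlation matrix across samples
#'
#' Correlates samples (columns) of an expression matrix, optionally on
#' the log2(FPKM + 1) scale. Zero-variance samples give `NA` entries and
#' are reported in the `"flagged_samples"` attribute rather than failing.
#'
#' @param expr genes x samples numeric matrix.
#' @param log_transform Use `log2(expr + 1)`; default TRUE.
#' @return samples x samples symmetric matrix with unit diagonal.
#' @export
pearson_correlation_matrix <- function(expr, log_transform = TRUE) {
  if (ncol(expr) < 2L) stop("need at least two samples")
  if (any(expr < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  m <- if (log_transform) log2(expr + 1) else expr
  sds <- apply(m, 2L, stats::sd)
  flagged <- colnames(m)[sds == 0]
  cc <- suppressWarnings(cor(m, method = "pearson"))
  diag(cc) <- 1
  attr(cc, "flagged_samples") <- flagged
  cc
}

#' Relative quantification by the 2^-ddCt method
#'
#' `2 ^ -((ct_target_t - ct_ref_t) - (ct_target_c - ct_ref_c))`:
#' target-gene Ct normalized to the reference gene (e.g. GAPDH) in
#' treatment versus control.
#'
#' @param ct_target_t,ct_ref_t Target and reference Ct in the treatment.
#' @param ct_target_c,ct_ref_c Target and reference Ct in the control.
#' @return Positive relative quantity (1 = no change).
#' @export
#' @examples
#' delta_delta_ct(25, 20, 24, 20)  # 0.5
delta_delta_ct <- function(ct_target_t, ct_ref_t, ct_target_c, ct_ref_c) {
  cts <- c(ct_target_t, ct_ref_t, ct_target_c, ct_ref_c)
  if (any(cts <= 0)) stop("Ct values must be positive")
  2 ^ -((ct_target_t - ct_ref_t) - (ct_target_c - ct_ref_c))
}

#' Two-group t-test on a gene's expression across sample groups
#'
#' Thin utility for stage-wise or group-wise comparison of a single
#' gene's expression, with the log transform configurable.
#'
#' @param expr Named numeric vector (expression per sample).
#' @param group_a,group_b Sample id vectors.
#' @param log_transform Compare on log2(x + 1); default TRUE.
#' @return `htest` object from [stats::t.test()].
#' @export
expression_group_test <- function(expr, group_a, group_b,
                                  log_transform = TRUE) {
  xa <- expr[group_a]; xb <- expr[group_b]
  if (log_transform) { xa <- log2(xa + 1); xb <- log2(xb + 1) }
  t.test(xa, xb)
}
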