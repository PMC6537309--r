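# Hypergeometric over-representation analysis over GMT-style gene sets
# with Benjamini-Hochberg FDR control.

#' Read gene sets from a GMT file
#'
#' @param path GMT path (set id, description, then member genes, tab
#'   separated).
#' @return Named list of character vectors (members per set), with set
#'   descriptions in attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lines <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
  desc <- setNames(vapply(lines, function(x) x[2L], character(1)),
                   vapply(lines, function(x) x[1L], character(1)))
  attr(sets, "descriptions") <- desc[names(sets)]
  sets
}

#' Hypergeometric gene-set over-representation test
#'
#' For each gene set, tests whether the query genes over-represent the
#' set relative to the universe: with `N` universe genes, `K` of them in
#' the set, and a query of size `n` containing `k` set members,
#' `p = P(X >= k)` under Hypergeometric(N, K, n) (upper tail — this is a
#' one-sided enrichment test). Sets are restricted to the universe
#' before testing; Benjamini-Hochberg adjustment is applied across all
#' tested sets.
#'
#' @param query Character vector of genes of interest (must lie in the
#'   universe).
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of background genes.
#' @param min_set_size Sets with fewer members in the universe are
#'   skipped. Default 1.
#' @return data.frame sorted by p-value with columns `set_id`, `k`, `n`,
#'   `K`, `N`, `p_value`, `fdr`.
#' @export
hypergeometric_enrichment <- function(query, sets, universe,
                                      min_set_size = 1L) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0L) stop("empty universe")
  if (length(query) == 0L) stop("empty query")
  if (!all(query %in% universe)) {
    stop("query genes outside the universe: ",
         paste(head(setdiff(query, universe), 3L), collapse = ", "))
  }
  N <- length(universe); n <- length(query)
  res <- lapply(names(sets), function(sid) {
    members <- intersect(sets[[sid]], universe)
    K <- length(members)
    if (K < min_set_size) return(NULL)
    k <- length(intersect(query, members))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = sid, k = k, n = n, K = K, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(set_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE))
  }
  out$fdr <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, returned in input order. Thin, validated
#' front end over [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order, capped at 1.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  p.adjust(p_values, method = "BH")
}
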