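# Enumeration and typing of alternative splicing events from a splice
# graph, plus evidence-driven discovery of novel events.
#
# Typing rules (documented in the methods vignette):
#  * ES  — exactly one exon skipped between two flanking model junctions
#          versus one skip junction.
#  * CE  — two or more consecutive exons skipped together as a cassette.
#  * A5SS/A3SS — two junctions sharing one boundary whose variable-side
#          exons overlap; the 5'/3' call is strand-aware.
#  * MXE — two internal, non-overlapping exons that never co-occur in any
#          transcript, spliced between a shared upstream donor and a
#          shared downstream acceptor.
#  * 5pMXE/3pMXE — the mutually exclusive pair are alternative first
#          (promoter-side) or last (polyadenylation-side) exons sharing
#          their single gene-body junction boundary.
#  * IR  — an annotated intron entirely contained within another
#          transcript's exon; the alternative path is the retained
#          intron, quantified from boundary reads rather than junctions.
#
# For every event the "model" path is the constitutive reference and the
# "alternative" path the variably used one: inclusion junctions are the
# model for skipping events; the shorter intron (splice site proximal to
# the exon) is the model for A5SS/A3SS; the transcript-5'-proximal exon
# is the model for MXE variants; the spliced junction is the model for IR.

EVENT_TYPES <- c("ES", "CE", "A5SS", "A3SS", "MXE", "5pMXE", "3pMXE", "IR")

empty_event_table <- function() {
  data.frame(event_id = character(), gene_id = character(),
             event_type = character(), known = logical(),
             chrom = character(), strand = character(),
             alt_start = integer(), alt_end = integer(),
             model_junctions = I(list()), alt_junctions = I(list()),
             stringsAsFactors = FALSE)
}

event_row <- function(gene_id, type, chrom, strand, alt_start, alt_end,
                      model, alt, known) {
  data.frame(event_id = NA_character_, gene_id = gene_id, event_type = type,
             known = known, chrom = chrom, strand = strand,
             alt_start = as.integer(alt_start), alt_end = as.integer(alt_end),
             model_junctions = I(list(sort(unique(model)))),
             alt_junctions = I(list(sort(unique(alt)))),
             stringsAsFactors = FALSE)
}

# Canonical order + ids; dedup by (type, model set, alt set).
finalize_events <- function(rows, gene_id) {
  if (length(rows) == 0L) return(empty_event_table())
  ev <- do.call(rbind, rows)
  mstr <- vapply(ev$model_junctions, paste, character(1), collapse = ";")
  astr <- vapply(ev$alt_junctions, paste, character(1), collapse = ";")
  ev <- ev[!duplicated(paste(ev$event_type, mstr, astr, sep = "|")), ,
           drop = FALSE]
  mstr <- vapply(ev$model_junctions, paste, character(1), collapse = ";")
  astr <- vapply(ev$alt_junctions, paste, character(1), collapse = ";")
  ord <- order(match(ev$event_type, EVENT_TYPES), ev$alt_start, ev$alt_end,
               mstr, astr)
  ev <- ev[ord, , drop = FALSE]
  ids <- sprintf("%s:%s:%s:%d-%d", ev$gene_id, ev$event_type, ev$chrom,
                 ev$alt_start, ev$alt_end)
  dup <- ave(seq_along(ids), ids, FUN = seq_along)
  ids[dup > 1L] <- paste0(ids[dup > 1L], "#", dup[dup > 1L])
  ev$event_id <- ids
  rownames(ev) <- NULL
  ev
}

#' Enumerate annotated alternative splicing events of one gene
#'
#' Compares the transcript junction chains of a splice graph pairwise and
#' emits every alternative-splicing event realized by the annotation,
#' typed as one of `ES`, `CE`, `A5SS`, `A3SS`, `MXE`, `5pMXE`, `3pMXE`
#' or `IR`. Events carry the model (constitutive) and alternative
#' junction sets used later for read counting, the genomic interval of
#' the variably included region, and `known = TRUE`. Enumeration is
#' deterministic and independent of transcript order.
#'
#' @param graph A `splice_graph` from [parse_annotation()].
#' @return An event table: data.frame with columns `event_id`, `gene_id`,
#'   `event_type`, `known`, `chrom`, `strand`, `alt_start`, `alt_end` and
#'   list-columns `model_junctions`, `alt_junctions` (junction keys).
#'   Single-transcript genes yield zero rows.
#' @export
enumerate_known_events <- function(graph) {
  stopifnot(inherits(graph, "splice_graph"))
  ex <- graph$exons
  chains <- graph$transcripts          # genomic-order exon indices
  if (length(chains) < 1L) return(empty_event_table())
  jdf <- parse_junction_key(graph$junctions)
  gid <- graph$gene_id; chrom <- graph$chrom; strand <- graph$strand
  rows <- list()
  add <- function(row) rows[[length(rows) + 1L]] <<- row

  ## --- skipping: ES (one exon) / CE (cassette of >= 2) -----------------
  for (chain in chains) {
    cex <- ex[chain, , drop = FALSE]
    n <- nrow(cex)
    if (n < 3L) next
    ckeys <- transcript_junctions(cex)
    for (r in seq_len(nrow(jdf))) {
      p <- which(cex$end == jdf$donor_end[r])
      q <- which(cex$start == jdf$acceptor_start[r])
      if (length(p) != 1L || length(q) != 1L || q - p < 2L) next
      skipped <- (p + 1L):(q - 1L)
      type <- if (length(skipped) == 1L) "ES" else "CE"
      add(event_row(gid, type, chrom, strand,
                    alt_start = cex$start[skipped[1L]],
                    alt_end = cex$end[skipped[length(skipped)]],
                    model = ckeys[p:(q - 1L)],
                    alt = graph$junctions[r], known = TRUE))
    }
  }

  ## --- alternative splice sites ---------------------------------------
  nj <- nrow(jdf)
  if (nj >= 2L) {
    overlap_exists <- function(edge_col, edge_vals) {
      # any pair of exons with the given fixed edges that overlap?
      e1 <- ex[ex[[edge_col]] == edge_vals[1L], , drop = FALSE]
      e2 <- ex[ex[[edge_col]] == edge_vals[2L], , drop = FALSE]
      any(outer(e1$start, e2$end, `<`) & outer(e1$end, e2$start, `>`))
    }
    for (i in seq_len(nj - 1L)) for (j in (i + 1L):nj) {
      same_acc <- jdf$acceptor_start[i] == jdf$acceptor_start[j]
      same_don <- jdf$donor_end[i] == jdf$donor_end[j]
      if (same_acc && !same_don) {
        d <- sort(c(jdf$donor_end[i], jdf$donor_end[j]))
        if (!overlap_exists("end", d)) next
        type <- if (strand == "+") "A5SS" else "A3SS"
        model <- graph$junctions[c(i, j)][which.max(c(jdf$donor_end[i], jdf$donor_end[j]))]
        alt <- setdiff(graph$junctions[c(i, j)], model)
        add(event_row(gid, type, chrom, strand, d[1L], d[2L], model, alt, TRUE))
      } else if (same_don && !same_acc) {
        a <- sort(c(jdf$acceptor_start[i], jdf$acceptor_start[j]))
        if (!overlap_exists("start", a)) next
        type <- if (strand == "+") "A3SS" else "A5SS"
        model <- graph$junctions[c(i, j)][which.min(c(jdf$acceptor_start[i], jdf$acceptor_start[j]))]
        alt <- setdiff(graph$junctions[c(i, j)], model)
        add(event_row(gid, type, chrom, strand, a[1L], a[2L], model, alt, TRUE))
      }
    }
  }

  ## --- mutually exclusive exon variants --------------------------------
  co <- exon_cooccurrence(chains, nrow(ex))
  tx <- seq_along(chains)
  for (ti in tx) for (tj in tx) {
    if (ti == tj) next
    ci <- chains[[ti]]; cj <- chains[[tj]]
    for (pi in seq_along(ci)) for (pj in seq_along(cj)) {
      A <- ci[pi]; B <- cj[pj]
      if (A >= B) next                       # unordered pair once (A left of B)
      if (co[A, B]) next                     # must never co-occur
      if (ex$end[A] > ex$start[B]) next      # must not overlap
      mx <- mxe_pattern(ex, ci, pi, cj, pj, strand)
      if (is.null(mx)) next
      # model = transcript-5'-proximal exon (left on '+', right on '-')
      model_is_A <- (strand == "+")
      add(event_row(gid, mx$type, chrom, strand,
                    alt_start = if (model_is_A) ex$start[B] else ex$start[A],
                    alt_end = if (model_is_A) ex$end[B] else ex$end[A],
                    model = if (model_is_A) mx$jA else mx$jB,
                    alt = if (model_is_A) mx$jB else mx$jA, known = TRUE))
    }
  }

  ## --- intron retention -------------------------------------------------
  for (r in seq_len(nrow(jdf))) {
    d <- jdf$donor_end[r]; a <- jdf$acceptor_start[r]
    if (any(ex$start < d & ex$end > a)) {
      add(event_row(gid, "IR", chrom, strand, d, a,
                    model = graph$junctions[r], alt = character(), known = TRUE))
    }
  }

  finalize_events(rows, gid)
}

exon_cooccurrence <- function(chains, n_exons) {
  co <- matrix(FALSE, n_exons, n_exons)
  for (chain in chains) co[chain, chain] <- TRUE
  co
}

# Classify the structural relation of exon A (position pi in genomic chain
# ci) and exon B (pj in cj) as an MXE variant; NULL when the flanking
# boundaries do not match. A is genomically left of B.
mxe_pattern <- function(ex, ci, pi, cj, pj, strand) {
  ni <- length(ci); nj <- length(cj)
  A <- ci[pi]; B <- cj[pj]
  has_prev <- pi > 1L && pj > 1L
  has_next <- pi < ni && pj < nj
  jk <- function(d, a) junction_key(ex$chrom[A], d, a, strand)
  if (has_prev && has_next) {
    dA <- ex$end[ci[pi - 1L]]; dB <- ex$end[cj[pj - 1L]]
    aA <- ex$start[ci[pi + 1L]]; aB <- ex$start[cj[pj + 1L]]
    if (dA == dB && aA == aB) {
      return(list(type = "MXE",
                  jA = c(jk(dA, ex$start[A]), jk(ex$end[A], aA)),
                  jB = c(jk(dB, ex$start[B]), jk(ex$end[B], aB))))
    }
    return(NULL)
  }
  first_i <- if (strand == "+") pi == 1L else pi == ni
  first_j <- if (strand == "+") pj == 1L else pj == nj
  last_i <- if (strand == "+") pi == ni else pi == 1L
  last_j <- if (strand == "+") pj == nj else pj == 1L
  if (first_i && first_j && ni > 1L && nj > 1L) {
    # alternative first exons joining the gene body at a shared boundary
    if (strand == "+") {
      aA <- ex$start[ci[2L]]; aB <- ex$start[cj[2L]]
      if (aA == aB && ex$end[A] < aA && ex$end[B] < aB) {
        return(list(type = "5pMXE", jA = jk(ex$end[A], aA), jB = jk(ex$end[B], aB)))
      }
    } else {
      dA <- ex$end[ci[ni - 1L]]; dB <- ex$end[cj[nj - 1L]]
      if (dA == dB && ex$start[A] > dA && ex$start[B] > dB) {
        return(list(type = "5pMXE", jA = jk(dA, ex$start[A]), jB = jk(dB, ex$start[B])))
      }
    }
  }
  if (last_i && last_j && ni > 1L && nj > 1L) {
    if (strand == "+") {
      dA <- ex$end[ci[ni - 1L]]; dB <- ex$end[cj[nj - 1L]]
      if (dA == dB && ex$start[A] > dA && ex$start[B] > dB) {
        return(list(type = "3pMXE", jA = jk(dA, ex$start[A]), jB = jk(dB, ex$start[B])))
      }
    } else {
      aA <- ex$start[ci[2L]]; aB <- ex$start[cj[2L]]
      if (aA == aB && ex$end[A] < aA && ex$end[B] < aB) {
        return(list(type = "3pMXE", jA = jk(ex$end[A], aA), jB = jk(ex$end[B], aB)))
      }
    }
  }
  NULL
}

#' Enumerate annotated events for many genes
#'
#' @param graphs Named list of splice graphs.
#' @return A single event table (rows from all genes).
#' @export
enumerate_all_known_events <- function(graphs) {
  evs <- lapply(graphs, enumerate_known_events)
  out <- do.call(rbind, c(evs, list(empty_event_table())))
  rownames(out) <- NULL
  out
}

#' Discover novel splicing events from unannotated junctions
#'
#' An observed junction absent from the gene's annotated junction set,
#' with at least `min_reads` supporting reads and matching the gene's
#' chromosome and strand, is typed against the annotation:
#' \itemize{
#'   \item both boundaries coincide with annotated exon edges but the
#'     combination is unannotated — a novel exon-skipping event (`ES`);
#'     the model junctions are the nearest annotated junctions sharing
#'     each boundary;
#'   \item one boundary shared with an annotated junction, the other
#'     shifted — a novel `A5SS`/`A3SS` (strand-aware; donor shift gives
#'     A5SS on `+`); the model is the nearest annotated junction sharing
#'     the anchored boundary (all of them when equidistant);
#'   \item no annotated anchor — the junction is an orphan, returned in
#'     the `"orphans"` attribute rather than as an event.
#' }
#'
#' @param graph A `splice_graph`.
#' @param evidence A [junction_evidence()] object.
#' @param min_reads Minimum read support for a novel junction. Default 2.
#' @return An event table with `known = FALSE`; orphan junction keys in
#'   attribute `"orphans"`.
#' @export
discover_novel_events <- function(graph, evidence, min_reads = 2L) {
  stopifnot(inherits(graph, "splice_graph"),
            inherits(evidence, "junction_evidence"))
  if (min_reads < 1L) stop("min_reads must be >= 1")
  keys <- names(evidence$counts)[evidence$counts >= min_reads]
  keys <- setdiff(keys, graph$junctions)
  if (length(keys) == 0L) {
    out <- empty_event_table(); attr(out, "orphans") <- character(); return(out)
  }
  obs <- parse_junction_key(keys)
  keep <- obs$chrom == graph$chrom & obs$strand == graph$strand
  # junctions outside the gene span are not this gene's business
  span <- range(c(graph$exons$start, graph$exons$end))
  keep <- keep & obs$donor_end >= span[1L] & obs$acceptor_start <= span[2L]
  obs <- obs[keep, , drop = FALSE]; keys <- keys[keep]
  if (nrow(obs) == 0L) {
    out <- empty_event_table(); attr(out, "orphans") <- character(); return(out)
  }
  jdf <- parse_junction_key(graph$junctions)
  ex <- graph$exons
  rows <- list(); orphans <- character()
  nearest <- function(cand_idx, dist) {
    graph$junctions[cand_idx[dist == min(dist)]]
  }
  for (r in seq_len(nrow(obs))) {
    d <- obs$donor_end[r]; a <- obs$acceptor_start[r]
    donor_at_edge <- any(ex$end == d)
    acceptor_at_edge <- any(ex$start == a)
    share_don <- which(jdf$donor_end == d)
    share_acc <- which(jdf$acceptor_start == a)
    if (donor_at_edge && acceptor_at_edge) {
      model <- c(if (length(share_don)) nearest(share_don, abs(jdf$acceptor_start[share_don] - a)),
                 if (length(share_acc)) nearest(share_acc, abs(jdf$donor_end[share_acc] - d)))
      rows[[length(rows) + 1L]] <- event_row(
        graph$gene_id, "ES", graph$chrom, graph$strand, d, a,
        model = model, alt = keys[r], known = FALSE)
    } else if (length(share_acc)) {
      type <- if (graph$strand == "+") "A5SS" else "A3SS"
      model <- nearest(share_acc, abs(jdf$donor_end[share_acc] - d))
      md <- parse_junction_key(model[1L])$donor_end
      rows[[length(rows) + 1L]] <- event_row(
        graph$gene_id, type, graph$chrom, graph$strand,
        min(d, md), max(d, md), model = model, alt = keys[r], known = FALSE)
    } else if (length(share_don)) {
      type <- if (graph$strand == "+") "A3SS" else "A5SS"
      model <- nearest(share_don, abs(jdf$acceptor_start[share_don] - a))
      ma <- parse_junction_key(model[1L])$acceptor_start
      rows[[length(rows) + 1L]] <- event_row(
        graph$gene_id, type, graph$chrom, graph$strand,
        min(a, ma), max(a, ma), model = model, alt = keys[r], known = FALSE)
    } else {
      orphans <- c(orphans, keys[r])
    }
  }
  out <- finalize_events(rows, graph$gene_id)
  attr(out, "orphans") <- orphans
  out
}

#' Count alternative and model junction reads per event
#'
#' Sums the evidence counts over each event's alternative and model
#' junction sets. For intron-retention events the alternative support is
#' the conservative minimum of the two exon-intron boundary counts of
#' the retained intron.
#'
#' @param events An event table.
#' @param evidence A [junction_evidence()] object for one sample.
#' @return data.frame with columns `event_id`, `alt_reads`, `model_reads`.
#' @export
count_event_reads <- function(events, evidence) {
  stopifnot(inherits(evidence, "junction_evidence"))
  sum_counts <- function(keys) {
    if (length(keys) == 0L) return(0L)
    sum(evidence$counts[keys], na.rm = TRUE)
  }
  alt <- mapply(function(keys, type, model_keys) {
    if (type == "IR") {
      bc <- evidence$boundary_counts
      hit <- match(model_keys[1L], bc$junction)
      if (is.na(hit)) 0L else min(bc$left[hit], bc$right[hit])
    } else sum_counts(keys)
  }, events$alt_junctions, events$event_type, events$model_junctions)
  model <- vapply(events$model_junctions, sum_counts, numeric(1))
  data.frame(event_id = events$event_id,
             alt_reads = as.integer(alt),
             model_reads = as.integer(model),
             stringsAsFactors = FALSE)
}

#' Write an event table to TSV
#'
#' Junction list-columns are serialized as `;`-joined key lists.
#'
#' @param events An event table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  out <- events
  out$model_junctions <- vapply(events$model_junctions, paste, character(1),
                                collapse = ";")
  out$alt_junctions <- vapply(events$alt_junctions, paste, character(1),
                              collapse = ";")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event table written by [write_event_table()]
#'
#' @param path TSV path.
#' @return An event table with junction list-columns restored.
#' @export
read_event_table <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  split_keys <- function(x) {
    lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
           function(v) v[nzchar(v)])
  }
  out$model_junctions <- I(split_keys(out$model_junctions))
  out$alt_junctions <- I(split_keys(out$alt_junctions))
  out
}
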