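# Synthetic data with planted ground truth. The generator builds toy
# annotations realizing each splicing-event type, draws junction read
# counts per sample from (beta-)binomial inclusion models, simulates
# FPKM matrices with planted fold changes, and can emit read-level SAM
# for the alignment-extraction path. Everything is seeded.

#' Generate a toy annotation with planted splicing events
#'
#' Builds one gene (two transcripts) per requested event instance, laid
#' out on non-overlapping coordinate blocks of one synthetic chromosome,
#' and returns the splice graphs together with an event-level truth
#' table giving the exact type, alternative region and model/alternative
#' junction sets each gene realizes. Gene strands alternate between `+`
#' and `-` so strand-aware typing is exercised.
#'
#' @param event_mix Named integer vector, instances per event type;
#'   names from `ES, CE, A5SS, A3SS, MXE, 5pMXE, 3pMXE, IR`.
#' @param seed Integer seed recorded in the truth table (the layout is
#'   fully deterministic).
#' @param gtf_path Optional path; when given the annotation is also
#'   written as GTF.
#' @param chrom Chromosome name, default `"chrS"`.
#' @return List with `graphs` (as from [parse_annotation()]), `truth`
#'   (data.frame: `gene_id`, `event_id`, `event_type`, `chrom`,
#'   `strand`, `alt_start`, `alt_end`, plus junction list-columns and
#'   `rng_seed`), and `gtf_path` (or `NA`).
#' @export
make_toy_annotation <- function(event_mix, seed = 1L, gtf_path = NULL,
                                chrom = "chrS") {
  if (is.null(names(event_mix)) || any(!nzchar(names(event_mix)))) {
    stop("event_mix must be named by event type")
  }
  bad <- setdiff(names(event_mix), EVENT_TYPES)
  if (length(bad)) stop("unknown event type in mix: ", paste(bad, collapse = ", "))
  if (any(event_mix < 0)) stop("event counts must be >= 0")
  types <- rep(names(event_mix), event_mix)
  if (length(types) == 0L) stop("event_mix requests no events")
  strands <- rep_len(c("+", "-"), length(types))
  offset <- 1000L + (seq_along(types) - 1L) * 10000L
  genes <- lapply(seq_along(types), function(i) {
    gene_id <- sprintf("gene%03d", i)
    tpl <- event_template(types[i], strands[i])
    list(gene_id = gene_id, strand = strands[i], offset = offset[i], tpl = tpl)
  })

  ex_rows <- do.call(rbind, lapply(genes, function(g) {
    do.call(rbind, lapply(seq_along(g$tpl$transcripts), function(ti) {
      tx <- g$tpl$transcripts[[ti]]
      data.frame(chrom = chrom, start = tx$start + g$offset,
                 end = tx$end + g$offset, strand = g$strand,
                 gene_id = g$gene_id,
                 transcript_id = sprintf("%s.t%d", g$gene_id, ti),
                 stringsAsFactors = FALSE)
    }))
  }))
  graphs <- lapply(split(ex_rows, ex_rows$gene_id), build_splice_graph)

  truth <- do.call(rbind, lapply(genes, function(g) {
    e <- g$tpl$expected
    shift <- function(j) {
      if (nrow(j) == 0L) return(character())
      junction_key(chrom, j[, 1L] + g$offset, j[, 2L] + g$offset, g$strand)
    }
    a0 <- as.integer(e$alt_region[1L] + g$offset)
    a1 <- as.integer(e$alt_region[2L] + g$offset)
    data.frame(gene_id = g$gene_id,
               event_id = sprintf("%s:%s:%s:%d-%d", g$gene_id, e$type,
                                  chrom, a0, a1),
               event_type = e$type, chrom = chrom, strand = g$strand,
               alt_start = a0, alt_end = a1,
               model_junctions = I(list(sort(shift(e$model)))),
               alt_junctions = I(list(sort(shift(e$alt)))),
               rng_seed = as.integer(seed),
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  if (!is.null(gtf_path)) write_annotation(graphs, gtf_path)
  list(graphs = graphs, truth = truth,
       gtf_path = if (is.null(gtf_path)) NA_character_ else gtf_path)
}

# Transcript structures (0-based, gene-relative) realizing one event of
# the given type on the given strand, with the expected event: the
# alternative region and model/alt junctions as the detector reports
# them. Junction matrices are (donor_end, acceptor_start) rows.
event_template <- function(type, strand) {
  ex <- function(s, e) data.frame(start = s, end = e)
  jx <- function(...) matrix(c(...), ncol = 2L, byrow = TRUE)
  plus <- strand == "+"
  switch(
    type,
    ES = list(
      transcripts = list(ex(c(0, 200, 400), c(100, 300, 500)),
                         ex(c(0, 400), c(100, 500))),
      expected = list(type = "ES", alt_region = c(200, 300),
                      model = jx(100, 200, 300, 400), alt = jx(100, 400))),
    CE = list(
      transcripts = list(ex(c(0, 200, 400, 600), c(100, 300, 500, 700)),
                         ex(c(0, 600), c(100, 700))),
      expected = list(type = "CE", alt_region = c(200, 500),
                      model = jx(100, 200, 300, 400, 500, 600),
                      alt = jx(100, 600))),
    A5SS = if (plus) list(
      transcripts = list(ex(c(0, 300), c(160, 400)), ex(c(0, 300), c(100, 400))),
      expected = list(type = "A5SS", alt_region = c(100, 160),
                      model = jx(160, 300), alt = jx(100, 300))
    ) else list(
      transcripts = list(ex(c(0, 240), c(100, 400)), ex(c(0, 300), c(100, 400))),
      expected = list(type = "A5SS", alt_region = c(240, 300),
                      model = jx(100, 240), alt = jx(100, 300))),
    A3SS = if (plus) list(
      transcripts = list(ex(c(0, 240), c(100, 400)), ex(c(0, 300), c(100, 400))),
      expected = list(type = "A3SS", alt_region = c(240, 300),
                      model = jx(100, 240), alt = jx(100, 300))
    ) else list(
      transcripts = list(ex(c(0, 300), c(160, 400)), ex(c(0, 300), c(100, 400))),
      expected = list(type = "A3SS", alt_region = c(100, 160),
                      model = jx(160, 300), alt = jx(100, 300))),
    MXE = list(
      transcripts = list(ex(c(0, 200, 600), c(100, 300, 700)),
                         ex(c(0, 400, 600), c(100, 500, 700))),
      expected = if (plus) {
        list(type = "MXE", alt_region = c(400, 500),
             model = jx(100, 200, 300, 600), alt = jx(100, 400, 500, 600))
      } else {
        list(type = "MXE", alt_region = c(200, 300),
             model = jx(100, 400, 500, 600), alt = jx(100, 200, 300, 600))
      }),
    `5pMXE` = if (plus) list(
      transcripts = list(ex(c(0, 400, 600), c(100, 500, 700)),
                         ex(c(200, 400, 600), c(300, 500, 700))),
      expected = list(type = "5pMXE", alt_region = c(200, 300),
                      model = jx(100, 400), alt = jx(300, 400))
    ) else list(
      transcripts = list(ex(c(0, 200, 400), c(100, 300, 500)),
                         ex(c(0, 200, 600), c(100, 300, 700))),
      expected = list(type = "5pMXE", alt_region = c(400, 500),
                      model = jx(300, 600), alt = jx(300, 400))),
    `3pMXE` = if (plus) list(
      transcripts = list(ex(c(0, 200, 400), c(100, 300, 500)),
                         ex(c(0, 200, 600), c(100, 300, 700))),
      expected = list(type = "3pMXE", alt_region = c(600, 700),
                      model = jx(300, 400), alt = jx(300, 600))
    ) else list(
      transcripts = list(ex(c(0, 400, 600), c(100, 500, 700)),
                         ex(c(200, 400, 600), c(300, 500, 700))),
      expected = list(type = "3pMXE", alt_region = c(0, 100),
                      model = jx(300, 400), alt = jx(100, 400))),
    IR = list(
      transcripts = list(ex(c(0, 200), c(100, 300)), ex(0, 300)),
      expected = list(type = "IR", alt_region = c(100, 200),
                      model = jx(100, 200), alt = jx(integer(0)))),
    stop("unsupported event type: ", type)
  )
}

#' Assign true inclusion ratios to events (the splicing truth table)
#'
#' Gives every event a per-condition true alternative-path inclusion
#' ratio (psi). Null events get `psi_a == psi_b` drawn uniformly from
#' `psi_null_range`; regulated events get a pair differing by exactly
#' `effect_size`, with the higher side assigned to condition a or b at
#' random (so planted regulation is balanced in direction).
#'
#' @param event_ids Character vector of event identifiers.
#' @param n_regulated Number of events planted as regulated (the first
#'   choice is made by seeded sampling, not list order).
#' @param effect_size Absolute psi difference planted in regulated
#'   events. Default 0.3.
#' @param psi_null_range Range for null psi draws. Default `c(0.2, 0.8)`.
#' @param psi_base_range Range for the lower psi of regulated pairs;
#'   default `c(0.15, 0.55)` so `psi + effect_size` stays inside (0, 1).
#' @param seed Integer seed, recorded per row.
#' @return data.frame: `event_id`, `psi_a`, `psi_b`, `planted_rase`,
#'   `rng_seed`.
#' @export
make_splicing_truth <- function(event_ids, n_regulated, effect_size = 0.3,
                                psi_null_range = c(0.2, 0.8),
                                psi_base_range = c(0.15, 0.55),
                                seed = 1L) {
  n <- length(event_ids)
  if (n_regulated > n) stop("n_regulated exceeds the number of events")
  if (effect_size < 0 || effect_size >= 1) stop("effect_size must be in [0, 1)")
  if (psi_base_range[2L] + effect_size >= 1) {
    stop("psi_base_range upper end + effect_size must stay below 1")
  }
  set.seed(seed)
  reg <- logical(n)
  reg[sample.int(n, n_regulated)] <- TRUE
  psi_a <- psi_b <- numeric(n)
  null_psi <- stats::runif(sum(!reg), psi_null_range[1L], psi_null_range[2L])
  psi_a[!reg] <- psi_b[!reg] <- null_psi
  base <- stats::runif(sum(reg), psi_base_range[1L], psi_base_range[2L])
  hi_in_b <- stats::runif(sum(reg)) < 0.5
  psi_a[reg] <- ifelse(hi_in_b, base, base + effect_size)
  psi_b[reg] <- ifelse(hi_in_b, base + effect_size, base)
  data.frame(event_id = event_ids, psi_a = psi_a, psi_b = psi_b,
             planted_rase = reg, rng_seed = as.integer(seed),
             stringsAsFactors = FALSE)
}

#' Simulate per-sample event read counts from a splicing truth table
#'
#' For each event and sample, draws the alternative-path read count as
#' Binomial(`depth_per_event`, psi) — Beta-Binomial when
#' `dispersion > 0`, with `dispersion` the intra-class correlation of
#' the beta mixing distribution — and assigns the remainder to the model
#' path.
#'
#' @param truth Output of [make_splicing_truth()].
#' @param depth_per_event Junction reads per event per sample.
#' @param n_samples_per_condition Samples in each of conditions a and b
#'   (scalar or length-2 vector).
#' @param dispersion Beta-binomial overdispersion in `[0, 1)`; 0 gives a
#'   pure binomial.
#' @param seed Integer seed.
#' @return Long data.frame: `event_id`, `sample_id`, `condition`,
#'   `alt_reads`, `model_reads`.
#' @export
simulate_event_counts <- function(truth, depth_per_event = 100L,
                                  n_samples_per_condition = 1L,
                                  dispersion = 0, seed = 1L) {
  if (depth_per_event < 1L) stop("depth_per_event must be >= 1")
  if (dispersion < 0 || dispersion >= 1) stop("dispersion must be in [0, 1)")
  if (any(truth$psi_a < 0 | truth$psi_a > 1 | truth$psi_b < 0 | truth$psi_b > 1)) {
    stop("psi values must lie in [0, 1]")
  }
  nn <- rep_len(n_samples_per_condition, 2L)
  set.seed(seed)
  draw <- function(psi, n_samples) {
    n <- length(psi) * n_samples
    p <- rep(psi, times = n_samples)
    if (dispersion > 0) {
      s <- (1 - dispersion) / dispersion
      a <- p * s; b <- (1 - p) * s
      degenerate <- p == 0 | p == 1
      p[!degenerate] <- rbeta(sum(!degenerate), a[!degenerate], b[!degenerate])
    }
    rbinom(n, depth_per_event, p)
  }
  out <- do.call(rbind, lapply(c("a", "b"), function(cond) {
    n_samp <- if (cond == "a") nn[1L] else nn[2L]
    psi <- if (cond == "a") truth$psi_a else truth$psi_b
    alt <- draw(psi, n_samp)
    data.frame(event_id = rep(truth$event_id, times = n_samp),
               sample_id = rep(sprintf("%s%d", cond, seq_len(n_samp)),
                               each = nrow(truth)),
               condition = cond,
               alt_reads = as.integer(alt),
               model_reads = as.integer(depth_per_event) - as.integer(alt),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate per-sample junction evidence over a toy annotation
#'
#' Draws event-level counts with [simulate_event_counts()] and
#' distributes them over each event's junction keys: alternative reads
#' over the alternative junctions, model reads evenly over the model
#' junctions (remainders to the first keys). Intron-retention support is
#' written to both boundary counts of the retained intron. Non-junction
#' filler coverage is implied by setting `total_mapped_fragments` so the
#' sample's junction-read fraction equals `junction_fraction`.
#'
#' @param annotation Output of [make_toy_annotation()].
#' @param truth Output of [make_splicing_truth()] over
#'   `annotation$truth$event_id`.
#' @param junction_fraction Planted junction-read fraction of each
#'   library. Default 0.2.
#' @inheritParams simulate_event_counts
#' @return List with `evidence` (list of [junction_evidence()]),
#'   `sample_sheet` (data.frame `sample_id`, `condition`) and
#'   `per_sample` event counts.
#' @export
simulate_junction_counts <- function(annotation, truth,
                                     depth_per_event = 100L,
                                     n_samples_per_condition = 1L,
                                     dispersion = 0, seed = 1L,
                                     junction_fraction = 0.2) {
  ev <- annotation$truth
  if (!setequal(truth$event_id, ev$event_id)) {
    stop("truth table does not cover the annotation's events")
  }
  per_sample <- simulate_event_counts(truth, depth_per_event,
                                      n_samples_per_condition, dispersion,
                                      seed)
  samples <- unique(per_sample[, c("sample_id", "condition")])
  spread <- function(total, keys) {
    k <- length(keys)
    base <- total %/% k
    extra <- total %% k
    setNames(base + (seq_len(k) <= extra), keys)
  }
  evidence <- lapply(seq_len(nrow(samples)), function(si) {
    sid <- samples$sample_id[si]
    cnt <- per_sample[per_sample$sample_id == sid, , drop = FALSE]
    cnt <- cnt[match(ev$event_id, cnt$event_id), , drop = FALSE]
    counts <- integer(); bjx <- character(); bl <- integer(); br <- integer()
    for (i in seq_len(nrow(ev))) {
      mk <- ev$model_junctions[[i]]
      counts <- c(counts, spread(cnt$model_reads[i], mk))
      if (ev$event_type[i] == "IR") {
        bjx <- c(bjx, mk[1L])
        bl <- c(bl, cnt$alt_reads[i]); br <- c(br, cnt$alt_reads[i])
      } else {
        counts <- c(counts, spread(cnt$alt_reads[i], ev$alt_junctions[[i]]))
      }
    }
    counts <- tapply(counts, names(counts), sum)
    counts <- setNames(as.integer(counts), names(counts))
    total <- round(sum(counts) / junction_fraction)
    junction_evidence(sid, counts,
                      boundary_counts = if (length(bjx)) {
                        data.frame(junction = bjx, left = bl, right = br,
                                   stringsAsFactors = FALSE)
                      } else NULL,
                      total_mapped_fragments = total)
  })
  names(evidence) <- samples$sample_id
  list(evidence = evidence,
       sample_sheet = data.frame(sample_id = samples$sample_id,
                                 condition = samples$condition,
                                 stringsAsFactors = FALSE),
       per_sample = per_sample)
}

#' Expression truth: per-gene condition means with planted fold changes
#'
#' @param gene_ids Character vector of gene ids.
#' @param n_deg Number of genes planted as differentially expressed.
#' @param fold_change Planted fold change (condition b over a); applied
#'   as `fc` or `1/fc` alternately so both directions occur.
#' @param mean_log2_range Base-mean log2(FPKM) range for uniform draws.
#' @param seed Integer seed.
#' @return data.frame: `gene_id`, `mean_a`, `mean_b`, `planted_deg`,
#'   `rng_seed`.
#' @export
make_expression_truth <- function(gene_ids, n_deg, fold_change = 2,
                                  mean_log2_range = c(2, 8), seed = 1L) {
  n <- length(gene_ids)
  if (n_deg > n) stop("n_deg exceeds the number of genes")
  if (fold_change <= 0) stop("fold_change must be positive")
  set.seed(seed)
  base <- 2 ^ stats::runif(n, mean_log2_range[1L], mean_log2_range[2L])
  deg <- logical(n); deg[sample.int(n, n_deg)] <- TRUE
  fc <- rep(1, n)
  up <- rep_len(c(TRUE, FALSE), sum(deg))
  fc[deg] <- ifelse(up, fold_change, 1 / fold_change)
  data.frame(gene_id = gene_ids, mean_a = base, mean_b = base * fc,
             planted_deg = deg, rng_seed = as.integer(seed),
             stringsAsFactors = FALSE)
}

#' Simulate an FPKM matrix around planted condition means
#'
#' Multiplicative log-normal noise: each entry is the condition mean
#' times `2^rnorm(0, noise_sd_log2)`. Zero noise reproduces the means
#' exactly.
#'
#' @param truth Output of [make_expression_truth()].
#' @param n_samples_per_condition Samples per condition (scalar or
#'   length 2).
#' @param noise_sd_log2 Standard deviation of the log2 noise. Default
#'   0.25.
#' @param seed Integer seed.
#' @return List with `expr` (genes x samples matrix) and `sample_sheet`.
#' @export
simulate_expression <- function(truth, n_samples_per_condition = 3L,
                                noise_sd_log2 = 0.25, seed = 1L) {
  if (any(truth$mean_a <= 0 | truth$mean_b <= 0)) stop("means must be > 0")
  nn <- rep_len(n_samples_per_condition, 2L)
  set.seed(seed)
  samples <- c(sprintf("a%d", seq_len(nn[1L])), sprintf("b%d", seq_len(nn[2L])))
  cond <- rep(c("a", "b"), nn)
  means <- cbind(matrix(truth$mean_a, nrow(truth), nn[1L]),
                 matrix(truth$mean_b, nrow(truth), nn[2L]))
  noise <- matrix(2 ^ rnorm(length(means), 0, noise_sd_log2),
                  nrow(truth), sum(nn))
  if (noise_sd_log2 == 0) noise[] <- 1
  expr <- means * noise
  dimnames(expr) <- list(truth$gene_id, samples)
  list(expr = expr,
       sample_sheet = data.frame(sample_id = samples, condition = cond,
                                 stringsAsFactors = FALSE))
}

#' Write junction evidence as single-end spliced SAM alignments
#'
#' Emits one uniquely mapped read per junction-count unit with a
#' `kM nN kM` CIGAR anchored `anchor` bases on each side, one
#' exon-body read per intron-retention boundary count crossing the
#' boundary by `anchor` bases, and unspliced filler reads (at the start
#' of the chromosome, clear of the genes) to reach
#' `total_mapped_fragments`. Extraction with
#' [extract_junctions_from_sam()] reproduces the evidence exactly.
#'
#' @param evidence A [junction_evidence()] object.
#' @param path Output SAM path.
#' @param anchor Aligned bases on each side of a junction or boundary.
#'   Default 50.
#' @return `path`, invisibly.
#' @export
write_evidence_sam <- function(evidence, path, anchor = 50L) {
  jdf <- parse_junction_key(names(evidence$counts))
  bdf <- evidence$boundary_counts
  ball <- if (nrow(bdf)) cbind(parse_junction_key(bdf$junction), bdf) else NULL
  chroms <- unique(c(jdf$chrom, if (!is.null(ball)) ball$chrom))
  maxpos <- vapply(chroms, function(ch) {
    max(0L, jdf$acceptor_start[jdf$chrom == ch],
        if (!is.null(ball)) ball$acceptor_start[ball$chrom == ch]) + 10000L
  }, numeric(1))
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", chroms, as.integer(maxpos)))
  rec <- list(); rid <- 0L
  emit <- function(chrom, pos1, cigar, n, strand = "+") {
    if (n <= 0L) return(invisible())
    flag <- if (strand == "-") 16L else 0L   # stranded library emulation
    ids <- rid + seq_len(n); rid <<- rid + n
    rec[[length(rec) + 1L]] <<- sprintf(
      "f%07d\t%d\t%s\t%d\t50\t%s\t*\t0\t0\t*\t*\tNH:i:1",
      ids, flag, chrom, pos1, cigar)
  }
  for (i in seq_len(nrow(jdf))) {
    intron <- jdf$acceptor_start[i] - jdf$donor_end[i]
    cigar <- sprintf("%dM%dN%dM", anchor, intron, anchor)
    emit(jdf$chrom[i], jdf$donor_end[i] - anchor + 1L, cigar,
         evidence$counts[i], jdf$strand[i])
  }
  if (!is.null(ball)) {
    for (i in seq_len(nrow(ball))) {
      cigar <- sprintf("%dM", 2L * anchor)
      emit(ball$chrom[i], ball$donor_end[i] - anchor + 1L, cigar,
           ball$left[i], ball$strand[i])
      emit(ball$chrom[i], ball$acceptor_start[i] - anchor + 1L, cigar,
           ball$right[i], ball$strand[i])
    }
  }
  filler <- evidence$total_mapped_fragments - rid
  if (filler > 0L && length(chroms)) {
    emit(chroms[1L], 10L, sprintf("%dM", 2L * anchor), filler)
  }
  recs <- unlist(rec, use.names = FALSE)
  # coordinate sort
  pos <- as.integer(vapply(strsplit(recs, "\t", fixed = TRUE), `[[`,
                           character(1), 4L))
  chr <- vapply(strsplit(recs, "\t", fixed = TRUE), `[[`, character(1), 3L)
  recs <- recs[order(chr, pos)]
  writeLines(c(lines, recs), path)
  invisible(path)
}
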