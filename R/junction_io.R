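# Per-sample junction evidence: reads spanning splice junctions, plus
# exon-intron boundary coverage used for intron retention.

#' Construct a junction evidence object
#'
#' Container for one sample's junction-spanning read counts. Most users
#' get these from [read_junction_bed()], [extract_junctions_from_sam()] or
#' [simulate_junction_counts()] rather than calling this directly.
#'
#' @param sample_id Sample identifier.
#' @param counts Named non-negative integer vector; names are junction
#'   keys (see [junction_key()]).
#' @param boundary_counts data.frame with columns `junction`, `left`,
#'   `right`: reads crossing the 5' (left) and 3' (right) exon-intron
#'   boundary of each annotated intron, for intron-retention evidence.
#' @param total_mapped_fragments Total uniquely mapped fragments in the
#'   sample (library size); defaults to the junction-count sum.
#' @return A `junction_evidence` object.
#' @export
junction_evidence <- function(sample_id, counts = integer(),
                              boundary_counts = NULL,
                              total_mapped_fragments = NULL) {
  if (length(counts)) {
    if (is.null(names(counts)) || any(counts < 0)) {
      stop("counts must be a named vector of non-negative integers")
    }
    counts <- counts[order(names(counts))]
  }
  if (is.null(boundary_counts)) {
    boundary_counts <- data.frame(junction = character(), left = integer(),
                                  right = integer(), stringsAsFactors = FALSE)
  }
  if (any(boundary_counts$left < 0) || any(boundary_counts$right < 0)) {
    stop("boundary counts must be non-negative")
  }
  if (is.null(total_mapped_fragments)) {
    total_mapped_fragments <- sum(counts)
  }
  if (total_mapped_fragments < 0) stop("total_mapped_fragments must be >= 0")
  structure(list(sample_id = sample_id,
                 counts = counts,
                 boundary_counts = boundary_counts,
                 total_mapped_fragments = as.numeric(total_mapped_fragments)),
            class = "junction_evidence")
}

#' @export
print.junction_evidence <- function(x, ...) {
  cat(sprintf("junction_evidence %s: %d junctions, %s junction reads, %s mapped fragments\n",
              x$sample_id, length(x$counts),
              format(sum(x$counts), big.mark = ","),
              format(x$total_mapped_fragments, big.mark = ",")))
  invisible(x)
}

#' Read TopHat-style BED12 junction counts
#'
#' Each record of a TopHat `junctions.bed`-dialect file describes one
#' junction as two blocks flanking the intron; the score column carries
#' the supporting read count. Records must have exactly two blocks.
#'
#' @param path BED12 file path.
#' @param sample_id Sample identifier for the returned evidence.
#' @return A [junction_evidence()] object (no boundary counts; BED
#'   junction files carry none).
#' @export
read_junction_bed <- function(path, sample_id) {
  if (!file.exists(path)) stop("junction BED not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(body) == 0L) return(junction_evidence(sample_id))
  nfield <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (any(nfield != 12L)) {
    stop("BED12 line ", which(nfield != 12L)[1L], ": expected 12 columns, got ",
         nfield[nfield != 12L][1L])
  }
  gr <- rtracklayer::import(path, format = "bed")
  score <- S4Vectors::mcols(gr)$score
  if (any(score < 0)) stop("negative junction read count in ", path)
  bl <- rtracklayer::blocks(gr)
  if (any(lengths(bl) != 2L)) {
    stop("junction BED record with != 2 blocks (line ",
         which(lengths(bl) != 2L)[1L], ")")
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  # blocks() returns absolute 1-based coordinates: the junction spans from
  # the end of block 1 to the start of block 2.
  donor_end <- vapply(bl, function(b) GenomicRanges::end(b)[1L], numeric(1))
  acceptor_start <- vapply(bl, function(b) GenomicRanges::start(b)[2L] - 1L,
                           numeric(1))
  keys <- junction_key(as.character(GenomicRanges::seqnames(gr)),
                       as.integer(donor_end), as.integer(acceptor_start),
                       strand)
  counts <- tapply(as.integer(score), keys, sum)
  junction_evidence(sample_id, setNames(as.integer(counts), names(counts)))
}

#' Extract junction counts from spliced SAM alignments
#'
#' Converts the SAM to BAM internally, then counts one junction support
#' per fragment per N gap whose flanking aligned blocks are both at least
#' `min_overhang` bases. Multimapped reads (NH tag > 1, or MAPQ below
#' `min_mapq` when NH is absent) are excluded; mates sharing a QNAME
#' contribute a given junction once. When `graphs` is supplied, reads
#' whose contiguous aligned blocks straddle an annotated exon-intron
#' boundary by `min_overhang` on each side are tallied as boundary counts
#' for intron-retention evidence.
#'
#' @param path SAM file path (header with \code{@SQ} lines required).
#' @param sample_id Sample identifier.
#' @param min_overhang Minimum aligned anchor on each side of a junction
#'   or boundary, in bases. Default 8.
#' @param graphs Optional splice graphs from [parse_annotation()]; enables
#'   boundary counting for the annotated introns.
#' @param min_mapq MAPQ threshold used only when the NH tag is missing.
#' @return A [junction_evidence()] object; `total_mapped_fragments` is the
#'   number of uniquely mapped fragments. The number of skipped
#'   unsupported-CIGAR reads is attached as attribute `"skipped_reads"`.
#' @export
extract_junctions_from_sam <- function(path, sample_id, min_overhang = 8L,
                                       graphs = NULL, min_mapq = 10L) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  if (min_overhang < 1L) stop("min_overhang must be >= 1")
  bam <- Rsamtools::asBam(path, tempfile("rasekit_sam_"),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  param <- Rsamtools::ScanBamParam(what = c("qname", "mapq"), tag = "NH")
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(ga) == 0L) return(junction_evidence(sample_id))
  nh <- S4Vectors::mcols(ga)$NH
  mapq <- S4Vectors::mcols(ga)$mapq
  unique_map <- ifelse(!is.na(nh), nh == 1L,
                       !is.na(mapq) & mapq >= min_mapq)
  cig <- GenomicAlignments::cigar(ga)
  ops <- GenomicAlignments::explodeCigarOps(cig)
  supported <- vapply(ops, function(o) all(o %in% c("M", "N", "D", "I", "S", "H", "=", "X")),
                      logical(1))
  n_skipped <- sum(!supported)
  if (n_skipped > 0L) {
    warning(n_skipped, " read(s) with unsupported CIGAR op skipped")
  }
  keep <- unique_map & supported
  ga <- ga[keep]
  total_fragments <- length(unique(S4Vectors::mcols(ga)$qname))
  if (length(ga) == 0L) {
    return(junction_evidence(sample_id, total_mapped_fragments = 0))
  }

  # Contiguous aligned blocks on the reference (N splits, D does not).
  blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    GenomicAlignments::cigar(ga), pos = GenomicRanges::start(ga),
    ops = c("M", "D", "=", "X"), reduce.ranges = TRUE)
  chrom <- as.character(GenomicRanges::seqnames(ga))
  strand <- as.character(GenomicRanges::strand(ga))
  strand[strand == "*"] <- "+"
  qname <- S4Vectors::mcols(ga)$qname

  jx <- junction_support_per_read(blocks, chrom, strand, qname, min_overhang)
  counts <- integer()
  if (nrow(jx)) {
    # one support per fragment per junction
    jx <- unique(jx)
    tab <- table(jx$key)
    counts <- setNames(as.integer(tab), names(tab))
  }

  boundary <- NULL
  if (!is.null(graphs)) {
    boundary <- boundary_counts_from_blocks(blocks, chrom, strand, qname,
                                            graphs, min_overhang)
  }
  ev <- junction_evidence(sample_id, counts, boundary,
                          total_mapped_fragments = total_fragments)
  attr(ev, "skipped_reads") <- n_skipped
  ev
}

# Junctions implied by the gaps between contiguous aligned blocks, with
# the anchor (flanking block width) filter applied per gap.
junction_support_per_read <- function(blocks, chrom, strand, qname,
                                      min_overhang) {
  nb <- lengths(blocks)
  spliced <- which(nb >= 2L)
  if (length(spliced) == 0L) {
    return(data.frame(qname = character(), key = character(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(spliced, function(i) {
    b <- blocks[[i]]
    s <- GenomicRanges::start(b); e <- GenomicRanges::end(b)
    w <- e - s + 1L
    k <- length(s)
    left_ok <- w[-k] >= min_overhang
    right_ok <- w[-1L] >= min_overhang
    ok <- left_ok & right_ok
    if (!any(ok)) return(NULL)
    data.frame(qname = qname[i],
               key = junction_key(chrom[i], e[-k][ok], s[-1L][ok] - 1L,
                                  strand[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(qname = character(), key = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

# Reads whose single aligned block covers [pos - min_overhang,
# pos + min_overhang) count as crossing the exon-intron boundary at pos.
boundary_counts_from_blocks <- function(blocks, chrom, strand, qname,
                                        graphs, min_overhang) {
  jdf <- do.call(rbind, lapply(unname(graphs), function(g) {
    if (length(g$junctions) == 0L) return(NULL)
    cbind(parse_junction_key(g$junctions), junction = g$junctions)
  }))
  if (is.null(jdf) || nrow(jdf) == 0L) return(NULL)
  jdf <- unique(jdf)

  flat <- unlist(blocks, use.names = FALSE)
  idx <- rep(seq_along(blocks), lengths(blocks))
  bdf <- data.frame(chrom = chrom[idx], strand = strand[idx],
                    qname = qname[idx],
                    start0 = GenomicRanges::start(flat) - 1L,
                    end0 = GenomicRanges::end(flat),
                    stringsAsFactors = FALSE)
  count_at <- function(pos, chr, str) {
    hits <- bdf$chrom == chr & bdf$strand == str &
      bdf$start0 <= pos - min_overhang & bdf$end0 >= pos + min_overhang
    length(unique(bdf$qname[hits]))
  }
  left <- mapply(count_at, jdf$donor_end, jdf$chrom, jdf$strand)
  right <- mapply(count_at, jdf$acceptor_start, jdf$chrom, jdf$strand)
  data.frame(junction = jdf$junction, left = as.integer(left),
             right = as.integer(right), stringsAsFactors = FALSE)
}

#' Report the junction-read fraction of a sample
#'
#' Junction-spanning reads divided by uniquely mapped fragments — the
#' standard library QC figure for spliced alignments.
#'
#' @param evidence A [junction_evidence()] object.
#' @return A single number in `[0, 1]`, or `NA` if no fragments mapped.
#' @export
junction_read_fraction <- function(evidence) {
  stopifnot(inherits(evidence, "junction_evidence"))
  if (evidence$total_mapped_fragments == 0) return(NA_real_)
  sum(evidence$counts) / evidence$total_mapped_fragments
}

#' Read a per-gene fragment-count table
#'
#' Tab-separated with columns `gene_id`, `count`, `length` (exon-model
#' length in nt, the union of the gene's exons).
#'
#' @param path TSV path.
#' @param sample_id Sample identifier.
#' @param total_mapped_fragments Library size; defaults to the count sum.
#' @return A `gene_counts` object: list with `sample_id`, `counts` and
#'   `exon_model_length` (both named by gene), `total_mapped_fragments`.
#' @export
read_gene_counts <- function(path, sample_id, total_mapped_fragments = NULL) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "count", "length")
  if (!all(need %in% names(df))) {
    stop("gene-count table must have columns gene_id, count, length")
  }
  gene_counts(sample_id, setNames(df$count, df$gene_id),
              setNames(df$length, df$gene_id), total_mapped_fragments)
}

#' @rdname read_gene_counts
#' @param counts Named non-negative vector of fragment counts per gene.
#' @param exon_model_length Named positive vector of exon-model lengths (nt).
#' @export
gene_counts <- function(sample_id, counts, exon_model_length,
                        total_mapped_fragments = NULL) {
  if (any(counts < 0)) stop("negative gene count")
  if (any(exon_model_length < 1)) stop("exon model length must be >= 1 nt")
  if (!setequal(names(counts), names(exon_model_length))) {
    stop("counts and exon_model_length must cover the same genes")
  }
  exon_model_length <- exon_model_length[names(counts)]
  if (is.null(total_mapped_fragments)) total_mapped_fragments <- sum(counts)
  structure(list(sample_id = sample_id, counts = counts,
                 exon_model_length = exon_model_length,
                 total_mapped_fragments = as.numeric(total_mapped_fragments)),
            class = "gene_counts")
}

#' FPKM from fragment counts
#'
#' Fragments per kilobase of exon model per million mapped fragments:
#' `count / (length/1000) / (total/1e6)`.
#'
#' @param gene_counts A `gene_counts` object (see [read_gene_counts()]).
#' @return Named numeric vector of FPKM values.
#' @export
#' @examples
#' gc <- gene_counts("s1", c(g1 = 1000), c(g1 = 2000),
#'                   total_mapped_fragments = 1e7)
#' fpkm(gc)  # 50
fpkm <- function(gene_counts) {
  stopifnot(inherits(gene_counts, "gene_counts"))
  total <- gene_counts$total_mapped_fragments
  if (total <= 0) stop("total_mapped_fragments must be > 0 to compute FPKM")
  gene_counts$counts / (gene_counts$exon_model_length / 1e3) / (total / 1e6)
}
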