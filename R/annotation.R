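# Annotation model: per-gene splice graphs built from GTF exon features.

#' Parse a GTF annotation into per-gene splice graphs
#'
#' Reads exon features from a GTF file (1-based inclusive coordinates,
#' `gene_id`/`transcript_id` attributes) and assembles one splice graph per
#' gene: the deduplicated exon set, the transcript exon chains, and the set
#' of annotated splice junctions (every consecutive-exon pair over all
#' transcripts, deduplicated). Internal coordinates are 0-based half-open.
#'
#' A junction whose key occurs in more than one gene's graph is recorded in
#' the `"ambiguous_junctions"` attribute of the returned list; it stays
#' assigned to every gene that contains it.
#'
#' @param gtf_path Path to a GTF file.
#' @return A named list of `splice_graph` objects keyed by `gene_id`. Each
#'   graph is a list with elements `gene_id`, `chrom`, `strand`, `exons`
#'   (data.frame `chrom`, `start`, `end`, `strand`, unique, sorted),
#'   `transcripts` (named list of integer vectors indexing `exons` in
#'   genomic order) and `junctions` (character vector of junction keys).
#' @seealso [junction_key()], [enumerate_known_events()]
#' @export
parse_annotation <- function(gtf_path) {
  if (!file.exists(gtf_path)) stop("annotation file not found: ", gtf_path)
  validate_gtf_lines(gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L) return(structure(list(), ambiguous_junctions = character()))
  md <- S4Vectors::mcols(gr)
  if (is.null(md$transcript_id) || anyNA(md$transcript_id) ||
      any(md$transcript_id == "")) {
    stop("exon feature without transcript_id attribute")
  }
  if (is.null(md$gene_id) || anyNA(md$gene_id) || any(md$gene_id == "")) {
    stop("exon feature without gene_id attribute")
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("exon feature with unstranded ('.') strand")
  ex <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = strand,
    gene_id = md$gene_id,
    transcript_id = md$transcript_id,
    stringsAsFactors = FALSE
  )
  graphs <- lapply(split(ex, ex$gene_id), build_splice_graph)
  dup <- table(unlist(lapply(graphs, `[[`, "junctions"), use.names = FALSE))
  structure(graphs, ambiguous_junctions = names(dup)[dup > 1L])
}

# Cheap structural pre-check so a malformed line is reported by number;
# rtracklayer's own errors do not carry one.
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^#", lines) & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 9L)) {
    stop("malformed GTF line ", which(body)[nfield < 9L][1L],
         ": expected 9 tab-separated fields")
  }
  invisible(TRUE)
}

build_splice_graph <- function(ex) {
  gene_id <- ex$gene_id[1L]
  exons <- unique(ex[, c("chrom", "start", "end", "strand")])
  exons <- exons[order(exons$chrom, exons$start, exons$end), , drop = FALSE]
  rownames(exons) <- NULL
  ekey <- paste(exons$chrom, exons$start, exons$end, exons$strand)
  transcripts <- lapply(split(ex, ex$transcript_id), function(tx) {
    tx <- tx[order(tx$start), , drop = FALSE]
    if (nrow(tx) > 1L) {
      if (length(unique(tx$chrom)) > 1L || length(unique(tx$strand)) > 1L) {
        stop("transcript ", tx$transcript_id[1L],
             " spans multiple chromosomes or strands")
      }
      if (any(tx$start[-1L] < tx$end[-nrow(tx)])) {
        stop("overlapping exons in transcript ", tx$transcript_id[1L])
      }
    }
    match(paste(tx$chrom, tx$start, tx$end, tx$strand), ekey)
  })
  junctions <- sort(unique(unlist(lapply(transcripts, function(idx) {
    transcript_junctions(exons[idx, , drop = FALSE])
  }), use.names = FALSE)))
  structure(
    list(gene_id = gene_id,
         chrom = exons$chrom[1L],
         strand = exons$strand[1L],
         exons = exons,
         transcripts = transcripts,
         junctions = junctions),
    class = "splice_graph"
  )
}

#' @export
print.splice_graph <- function(x, ...) {
  cat(sprintf("splice_graph %s (%s%s): %d exons, %d transcripts, %d junctions\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons),
              length(x$transcripts), length(x$junctions)))
  invisible(x)
}

#' Count unique annotated exons across splice graphs
#'
#' Exons shared by several transcripts (or genes) are counted once, by
#' identity of (chrom, start, end, strand). Used to report detection
#' coverage of the annotation against junction evidence.
#'
#' @param graphs A list of `splice_graph` objects from [parse_annotation()].
#' @return Integer count of distinct exons.
#' @export
annotated_exon_count <- function(graphs) {
  if (length(graphs) == 0L) return(0L)
  all_ex <- do.call(rbind, lapply(graphs, `[[`, "exons"))
  nrow(unique(all_ex))
}

#' Write splice graphs back to GTF
#'
#' Emits one exon feature per transcript exon, restoring 1-based inclusive
#' GTF coordinates. Re-parsing the output reproduces the same junction
#' sets (round-trip identity).
#'
#' @param graphs List of `splice_graph` objects.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(graphs, path) {
  rows <- lapply(unname(graphs), function(g) {
    do.call(rbind, lapply(names(g$transcripts), function(tid) {
      ex <- g$exons[g$transcripts[[tid]], , drop = FALSE]
      data.frame(chrom = ex$chrom, start = ex$start, end = ex$end,
                 strand = ex$strand, gene_id = g$gene_id,
                 transcript_id = tid, stringsAsFactors = FALSE)
    }))
  })
  ex <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand
  )
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$source <- "rasekit"
  S4Vectors::mcols(gr)$gene_id <- ex$gene_id
  S4Vectors::mcols(gr)$transcript_id <- ex$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
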