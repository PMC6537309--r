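# Independent oracles and fixture builders shared across tests.
# Oracles are written from first principles (choose(), hand step-up,
# exhaustive enumeration) so they share no code path with the package.

# Two-sided Fisher p by direct combinatorial enumeration.
oracle_fisher2x2 <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c; n2 <- b + d
  N <- m1 + m2
  if (m1 == 0 || m2 == 0 || n1 == 0 || n2 == 0) return(1)
  ks <- max(0, n1 - m2):min(m1, n1)
  pr <- choose(m1, ks) * choose(m2, n1 - ks) / choose(N, n1)
  po <- choose(m1, a) * choose(m2, c) / choose(N, n1)
  min(1, sum(pr[pr <= po * (1 + 1e-7)]))
}

# Hypergeometric upper tail P(X >= k) by enumeration with choose().
oracle_hyper_upper <- function(k, N, K, n) {
  ks <- k:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Benjamini-Hochberg step-up, written out literally.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(1, adj)[order(o)]
}

# All 2x2 tables with grand total exactly `tot`.
all_tables_with_total <- function(tot) {
  out <- vector("list", 0L)
  for (a in 0:tot) for (b in 0:(tot - a)) for (cc in 0:(tot - a - b)) {
    out[[length(out) + 1L]] <- c(a, b, cc, tot - a - b - cc)
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("a", "b", "c", "d")
  m
}

all_event_types <- c("ES", "CE", "A5SS", "A3SS", "MXE", "5pMXE", "3pMXE", "IR")

one_of_each_mix <- function() {
  stats::setNames(rep(1L, length(all_event_types)), all_event_types)
}

# Three-gene GTF fixture written by hand (1-based inclusive coordinates):
# gA: 2 transcripts sharing exons 101-200/301-400, one adding 501-600
#     -> junctions (200,300), (400,500): 2 junctions, 3 unique exons
# gB: 1 transcript, exons 1101-1200, 1301-1400 -> 1 junction
# gC: 2 transcripts over the same exon set 2101-2200/2301-2400
#     -> 1 deduplicated junction, 2 unique exons
write_three_gene_gtf <- function(path) {
  fmt <- "chr1\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";"
  lines <- c(
    sprintf(fmt, 101, 200, "+", "gA", "gA.t1"),
    sprintf(fmt, 301, 400, "+", "gA", "gA.t1"),
    sprintf(fmt, 101, 200, "+", "gA", "gA.t2"),
    sprintf(fmt, 301, 400, "+", "gA", "gA.t2"),
    sprintf(fmt, 501, 600, "+", "gA", "gA.t2"),
    sprintf(fmt, 1101, 1200, "-", "gB", "gB.t1"),
    sprintf(fmt, 1301, 1400, "-", "gB", "gB.t1"),
    sprintf(fmt, 2101, 2200, "+", "gC", "gC.t1"),
    sprintf(fmt, 2301, 2400, "+", "gC", "gC.t1"),
    sprintf(fmt, 2101, 2200, "+", "gC", "gC.t2"),
    sprintf(fmt, 2301, 2400, "+", "gC", "gC.t2")
  )
  writeLines(lines, path)
  path
}

# BED12 junction fixture: 5 records with known counts.
write_five_junction_bed <- function(path) {
  rec <- function(chrom, start, end, name, score, strand, b1, b2, off2) {
    sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t255,0,0\t2\t%d,%d\t0,%d",
            chrom, start, end, name, score, strand, start, end, b1, b2, off2)
  }
  writeLines(c(
    rec("chr1", 1000, 1200, "J1", 7, "+", 50, 50, 150),
    rec("chr1", 2000, 2300, "J2", 12, "+", 40, 60, 240),
    rec("chr1", 3000, 3500, "J3", 3, "-", 50, 50, 450),
    rec("chr2", 100, 400, "J4", 25, "+", 20, 20, 280),
    rec("chr2", 900, 1300, "J5", 1, "-", 30, 30, 370)
  ), path)
  path
}
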