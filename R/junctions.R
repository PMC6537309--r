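# Junction identity and key arithmetic.
#
# A junction is identified by (chrom, donor_end, acceptor_start, strand)
# in 0-based half-open coordinates: `donor_end` is one past the last base
# of the genomically-left exon, `acceptor_start` the first base of the
# genomically-right exon, so donor_end < acceptor_start and the intron
# occupies [donor_end, acceptor_start). Donor/acceptor *roles* are
# strand-aware: on '-' the biological donor is the right edge.

#' Build junction identity keys
#'
#' Encodes junctions as `"chrom:donor_end:acceptor_start:strand"` strings,
#' the identity used throughout for counting and set comparisons.
#'
#' @param chrom Character vector of chromosome names.
#' @param donor_end Integer vector, 0-based exclusive end of the left exon.
#' @param acceptor_start Integer vector, 0-based start of the right exon.
#' @param strand Character vector, `"+"` or `"-"`.
#' @return Character vector of junction keys.
#' @export
#' @examples
#' junction_key("chr1", 200L, 300L, "+")
junction_key <- function(chrom, donor_end, acceptor_start, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  if (any(donor_end >= acceptor_start)) {
    stop("junction must satisfy donor_end < acceptor_start")
  }
  paste(chrom, donor_end, acceptor_start, strand, sep = ":")
}

#' Decode junction keys into a data frame
#'
#' Inverse of [junction_key()].
#'
#' @param keys Character vector of junction keys.
#' @return A data.frame with columns `chrom`, `donor_end`,
#'   `acceptor_start`, `strand`.
#' @export
parse_junction_key <- function(keys) {
  if (length(keys) == 0L) {
    return(data.frame(chrom = character(), donor_end = integer(),
                      acceptor_start = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, ":", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) stop("malformed junction key: ", keys[which(bad)[1L]])
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  data.frame(chrom = m[, 1L],
             donor_end = as.integer(m[, 2L]),
             acceptor_start = as.integer(m[, 3L]),
             strand = m[, 4L],
             stringsAsFactors = FALSE)
}

# Consecutive-exon junction keys for one transcript. `exons` is a
# data.frame (chrom, start, end, strand) already sorted by genomic start.
transcript_junctions <- function(exons) {
  n <- nrow(exons)
  if (n < 2L) return(character())
  junction_key(exons$chrom[-n], exons$end[-n], exons$start[-1L],
               exons$strand[-n])
}
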