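# Internal coordinate convention: 0-based half-open everywhere in memory.
# GTF (1-based closed) and SAM (1-based) are converted at file boundaries only.

#' Construct an aligned read
#'
#' In-memory representation of one spliced long-read alignment: strand-aware
#' exon blocks in 0-based half-open genomic coordinates plus the per-read
#' polyadenylation call.
#'
#' @param read_id Read identifier.
#' @param chrom Chromosome / contig name.
#' @param strand Transcript strand, `"+"` or `"-"`.
#' @param starts,ends Integer vectors of exon block starts (0-based,
#'   inclusive) and ends (exclusive), strictly increasing and non-overlapping;
#'   consecutive blocks must be separated by at least 1 bp (each gap is an
#'   intron).
#' @param polya One of `"polyadenylated"`, `"not_polyadenylated"`,
#'   `"unknown"`.
#' @param mapq Mapping quality.
#' @return A list of class `aligned_read`.
#' @export
aligned_read <- function(read_id, chrom, strand, starts, ends,
                         polya = "unknown", mapq = 60L) {
  starts <- as.integer(starts); ends <- as.integer(ends)
  stopifnot(length(starts) >= 1L, length(starts) == length(ends),
            nzchar(chrom), strand %in% c("+", "-"),
            all(starts < ends), all(starts >= 0L))
  if (length(starts) > 1L && any(starts[-1L] <= ends[-length(ends)]))
    stop("exon blocks must be separated by >= 1 bp gaps: ", read_id)
  structure(list(read_id = read_id, chrom = chrom, strand = strand,
                 starts = starts, ends = ends, polya = polya,
                 mapq = as.integer(mapq)),
            class = "aligned_read")
}

#' Construct a transcript model
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom,strand Location; strand `"+"` or `"-"`.
#' @param starts,ends Exon blocks, 0-based half-open, strictly increasing.
#' @param source `"reference"` or `"assembled"`.
#' @return A list of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             starts, ends, source = "reference") {
  starts <- as.integer(starts); ends <- as.integer(ends)
  stopifnot(length(starts) >= 1L, length(starts) == length(ends),
            all(starts < ends))
  if (length(starts) > 1L && any(starts[-1L] < ends[-length(ends)]))
    stop("overlapping exons in transcript ", transcript_id)
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand,
                 starts = starts, ends = ends, source = source),
            class = "transcript_model")
}

# intron coordinates of an exon-block structure: list(starts, ends) where
# intron i = [ends[i], starts[i+1]) of the exon blocks
intron_coords <- function(starts, ends) {
  n <- length(starts)
  if (n < 2L) return(list(starts = integer(0), ends = integer(0)))
  list(starts = ends[-n], ends = starts[-1L])
}

# canonical string key for an intron chain; empty chain -> trailing "|"
chain_key <- function(chrom, strand, istarts, iends) {
  paste0(chrom, "|", strand, "|",
         paste(istarts, iends, sep = "-", collapse = ","))
}

junction_keys <- function(chrom, strand, istarts, iends) {
  if (length(istarts) == 0L) return(character(0))
  paste0(chrom, "|", strand, "|", istarts, "-", iends)
}

read_chain_key <- function(read) {
  ic <- intron_coords(read$starts, read$ends)
  chain_key(read$chrom, read$strand, ic$starts, ic$ends)
}

# strand-aware 5' end (TSS side) of an exon-block structure, 0-based.
# On "+" this is the start of the first block; on "-" the (exclusive) end of
# the last block, matching the convention that a minus-strand transcript with
# blocks [0,100),[200,300) has TSS 300 and TES 0.
five_prime_end <- function(strand, starts, ends) {
  if (strand == "+") starts[1L] else ends[length(ends)]
}

three_prime_end <- function(strand, starts, ends) {
  if (strand == "+") ends[length(ends)] else starts[1L]
}

# reciprocal overlap fraction of two intervals [s1,e1) and [s2,e2)
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2)
  if (ov <= 0) return(0)
  min(ov / (e1 - s1), ov / (e2 - s2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
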