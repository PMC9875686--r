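#' Parse spliced long-read alignments from SAM/BAM
#'
#' Reads primary alignments and converts each into an [aligned_read()]:
#' exon blocks are obtained by walking the CIGAR on the reference
#' (`M`/`=`/`X`/`D` extend the current block, `N` closes it and opens the
#' next, `I`/`S`/`H` consume no reference). Secondary, supplementary and
#' unmapped records are skipped.
#'
#' The transcript strand is taken from the spliced-strand tag (`ts`, as
#' written by minimap2: `+` means the transcript strand equals the alignment
#' strand, `-` the opposite) when present, otherwise from the alignment
#' strand. Direct RNA-seq reads are stranded, but aligners differ in tagging.
#'
#' @param path SAM or BAM file. A `.sam` file is converted to BAM on the fly.
#' @param min_mapq Minimum mapping quality; alignments below it are dropped.
#' @param polya Optional poly(A) call table from [parse_polya_table()]; when
#'   supplied, per-read polyadenylation states are attached.
#' @return List of [aligned_read()] objects (0-based half-open exon blocks).
#' @export
parse_alignments <- function(path, min_mapq = 1L, polya = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE),
    what = c("mapq"), tag = "ts",
    mapqFilter = min_mapq)
  gal <- GenomicAlignments::readGAlignments(bam, param = param,
                                            use.names = TRUE)
  if (length(gal) == 0L) return(list())
  blocks <- GenomicAlignments::extractAlignmentRangesOnReference(
    GenomicAlignments::cigar(gal), BiocGenerics::start(gal),
    drop.D.ranges = FALSE)
  chroms <- as.character(GenomicRanges::seqnames(gal))
  astrand <- as.character(BiocGenerics::strand(gal))
  ts <- S4Vectors::mcols(gal)$ts
  mapq <- S4Vectors::mcols(gal)$mapq
  starts_l <- as.list(BiocGenerics::start(blocks))
  ends_l <- as.list(BiocGenerics::end(blocks))
  ids <- names(gal)
  out <- vector("list", length(gal))
  for (i in seq_along(gal)) {
    strand <- astrand[i]
    if (!is.null(ts) && !is.na(ts[i]) && ts[i] == "-")
      strand <- if (strand == "+") "-" else "+"
    if (!strand %in% c("+", "-")) strand <- "+"
    out[[i]] <- aligned_read(
      read_id = ids[i], chrom = chroms[i], strand = strand,
      starts = starts_l[[i]] - 1L, ends = ends_l[[i]],
      mapq = mapq[i])
  }
  if (!is.null(polya)) out <- attach_polya(out, polya)
  out
}

#' Attach poly(A) calls to reads
#'
#' @param reads List of [aligned_read()].
#' @param polya A table from [parse_polya_table()].
#' @return Reads with `polya` set to the table's state, or `"unknown"` for
#'   reads absent from the table.
#' @export
attach_polya <- function(reads, polya) {
  lapply(reads, function(r) {
    st <- polya[[r$read_id]]
    r$polya <- if (is.null(st)) "unknown" else st
    r
  })
}

#' Parse a reference annotation (GTF)
#'
#' Keeps `exon` features, groups them by `transcript_id`, sorts exons and
#' converts 1-based closed GTF coordinates to the internal 0-based half-open
#' convention. Exons without a `transcript_id` and transcripts with
#' overlapping exons are skipped with a warning.
#'
#' @param path GTF file.
#' @return List of [transcript_model()] objects.
#' @export
parse_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("cannot parse GTF: ",
                                          conditionMessage(e)))
  if (length(gr) == 0L) return(list())
  gr <- gr[!is.na(S4Vectors::mcols(gr)$type) &
             as.character(S4Vectors::mcols(gr)$type) == "exon"]
  if (length(gr) == 0L) return(list())
  txid <- S4Vectors::mcols(gr)$transcript_id
  bad <- is.na(txid) | !nzchar(txid)
  if (any(bad)) {
    warning(sum(bad), " exon record(s) without transcript_id skipped")
    gr <- gr[!bad]; txid <- txid[!bad]
  }
  gid <- S4Vectors::mcols(gr)$gene_id
  if (is.null(gid)) gid <- rep(NA_character_, length(gr))
  df <- data.frame(
    tx = txid, gene = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr) - 1L,  # to 0-based half-open
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE)
  out <- list()
  for (tx in unique(df$tx)) {
    sub <- df[df$tx == tx, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    n <- nrow(sub)
    if (n > 1L && any(sub$start[-1L] < sub$end[-n])) {
      warning("transcript ", tx, " has overlapping exons; skipped")
      next
    }
    strand <- sub$strand[1L]
    if (!strand %in% c("+", "-")) strand <- "+"
    out[[tx]] <- transcript_model(
      transcript_id = tx,
      gene_id = if (is.na(sub$gene[1L])) tx else sub$gene[1L],
      chrom = sub$chrom[1L], strand = strand,
      starts = sub$start, ends = sub$end, source = "reference")
  }
  unname(out)
}

#' Parse per-read polyadenylation calls
#'
#' Default column layout follows the nanopolish-polya output (a header line
#' with `readname` and `qc_tag` columns). Reads whose QC tag equals
#' `pass_tag` are `polyadenylated`; every other listed read is
#' `not_polyadenylated`; reads absent from the table are `unknown` at lookup
#' time.
#'
#' @param path TSV file.
#' @param read_col,qc_col Column names holding the read identifier and QC tag.
#' @param pass_tag QC value counted as a confirmed poly(A) tail.
#' @return Named list mapping read_id to
#'   `"polyadenylated"`/`"not_polyadenylated"`, of class `polya_table`.
#' @export
parse_polya_table <- function(path, read_col = "readname", qc_col = "qc_tag",
                              pass_tag = "PASS") {
  if (!file.exists(path)) stop("poly(A) table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c(read_col, qc_col) %in% names(df)))
    stop("poly(A) table lacks columns ", read_col, "/", qc_col)
  ids <- as.character(df[[read_col]])
  dup <- duplicated(ids)
  if (any(dup)) {
    warning(sum(dup), " duplicate read_id(s) in poly(A) table; keeping first")
    df <- df[!dup, , drop = FALSE]; ids <- ids[!dup]
  }
  states <- ifelse(df[[qc_col]] == pass_tag,
                   "polyadenylated", "not_polyadenylated")
  structure(as.list(stats::setNames(states, ids)), class = "polya_table")
}

#' Parse a BED file of peaks (CAGE/SAGE or poly(A) clusters)
#'
#' @param path BED file (0-based half-open).
#' @param label Peak type: `"cage"`, `"sage"` or `"polya_cluster"`.
#' @return A `peak_set`: data.frame with chrom/start/end/strand plus a label
#'   attribute. Strand is `"."` when the BED has none.
#' @export
parse_peaks <- function(path, label = c("cage", "sage", "polya_cluster")) {
  label <- match.arg(label)
  if (!file.exists(path)) stop("peak file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  peak_set(df, label)
}

#' Build a peak set from a data frame
#'
#' @param df data.frame with columns chrom, start, end (0-based half-open)
#'   and optionally strand.
#' @param label Peak type label.
#' @return A `peak_set` object.
#' @export
peak_set <- function(df, label = "cage") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (is.null(df$strand)) df$strand <- "."
  stopifnot(all(df$start < df$end))
  structure(df[, c("chrom", "start", "end", "strand")],
            label = label, class = c("peak_set", "data.frame"))
}

# is a genomic point within any peak extended by +/- window?
# Strand is compared only when both the peak and the query carry one.
point_in_peaks <- function(peaks, chrom, pos, window = 0L, strand = NULL) {
  if (is.null(peaks) || nrow(peaks) == 0L) return(FALSE)
  hit <- peaks$chrom == chrom &
    pos >= (peaks$start - window) & pos < (peaks$end + window)
  if (!is.null(strand)) hit <- hit & (peaks$strand == "." | peaks$strand == strand)
  any(hit)
}

#' Write isoform calls to a GTF file
#'
#' Emits one `transcript` feature and its `exon` features per isoform, in
#' 1-based closed GTF coordinates, with `transcript_id`, `gene_id`,
#' `read_support`, and `category` attributes. The output round-trips through
#' [parse_annotation()] losslessly at the exon-structure level.
#'
#' @param isoforms List of isoform calls (or [transcript_model()]s).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_isoform_gtf <- function(isoforms, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 2", con)
  for (iso in isoforms) {
    attrs <- sprintf('transcript_id "%s"; gene_id "%s";',
                     iso$transcript_id, iso$gene_id %||% iso$transcript_id)
    if (!is.null(iso$n_reads))
      attrs <- paste0(attrs, sprintf(' read_support "%d";', iso$n_reads))
    if (!is.null(iso$category))
      attrs <- paste0(attrs, sprintf(' category "%s";', iso$category))
    n <- length(iso$starts)
    lines <- c(
      paste(iso$chrom, "isoforge", "transcript",
            iso$starts[1L] + 1L, iso$ends[n], ".", iso$strand, ".",
            attrs, sep = "\t"),
      paste(iso$chrom, "isoforge", "exon",
            iso$starts + 1L, iso$ends, ".", iso$strand, ".",
            attrs, sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}
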