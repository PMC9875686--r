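# Independent brute-force oracles and small fixture builders. Every oracle
# here is written from the format definition directly and shares no code
# with the package implementation.

# Brute-force CIGAR interpreter: walk operation by operation, M/=/X/D move
# the reference cursor, N ends the current block, everything else is ignored
# on the reference.
oracle_cigar_blocks <- function(cigar, pos0) {
  m <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]$", "", m))
  ops <- sub("^[0-9]+", "", m)
  starts <- integer(0); ends <- integer(0)
  block_start <- pos0; cur <- pos0
  for (i in seq_along(ops)) {
    if (ops[i] %in% c("M", "=", "X", "D")) {
      cur <- cur + lens[i]
    } else if (ops[i] == "N") {
      starts <- c(starts, block_start); ends <- c(ends, cur)
      cur <- cur + lens[i]
      block_start <- cur
    }
  }
  list(starts = c(starts, block_start), ends = c(ends, cur))
}

# random valid spliced CIGAR: M segments joined by I/D/N, optional soft clips
random_cigar <- function() {
  n_seg <- sample(1:5, 1)
  parts <- character(0)
  if (runif(1) < 0.3) parts <- paste0(sample(1:20, 1), "S")
  for (i in seq_len(n_seg)) {
    parts <- c(parts, paste0(sample(1:80, 1), "M"))
    if (i < n_seg)
      parts <- c(parts, paste0(sample(20:500, 1),
                               sample(c("N", "D", "I"), 1,
                                      prob = c(0.6, 0.2, 0.2))))
  }
  if (runif(1) < 0.3) parts <- c(parts, paste0(sample(1:20, 1), "S"))
  paste(parts, collapse = "")
}

# write a SAM file from (read_id, pos0, cigar) rows; SEQ is left as '*'
write_fixture_sam <- function(df, path, chrom = "chrFix", chrom_len = 1e6,
                              flag = 0L, mapq = 60L, extra = "ts:A:+") {
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, as.integer(chrom_len)))
  df <- df[order(df$pos0), , drop = FALSE]
  lines <- c(lines, paste(df$read_id, flag, chrom, df$pos0 + 1L, mapq,
                          df$cigar, "*", 0L, 0L, "*", "*", extra,
                          sep = "\t"))
  writeLines(lines, path)
  path
}

# brute-force nearest site: linear scan, ties to the smaller coordinate
oracle_nearest <- function(sites, pos) {
  if (length(sites) == 0) return(NULL)
  d <- abs(sites - pos)
  i <- which(d == min(d))
  best <- min(sites[i])
  list(site = best, distance = abs(best - pos))
}

# brute-force junction support: enumerate every read's introns
oracle_junction_support <- function(reads) {
  keys <- character(0)
  for (r in reads) {
    n <- length(r$starts)
    if (n < 2) next
    keys <- c(keys, paste0(r$chrom, "|", r$strand, "|",
                           r$ends[-n], "-", r$starts[-1]))
  }
  if (length(keys) == 0) return(integer(0))
  tab <- table(keys)
  setNames(as.integer(tab), names(tab))
}

# brute-force matcher: all-pairs comparison of intron chains
oracle_match <- function(iso, refs) {
  iso_chain <- function(t) {
    n <- length(t$starts)
    if (n < 2) return("")
    paste(t$ends[-n], t$starts[-1], sep = "-", collapse = ",")
  }
  hits <- character(0)
  for (r in refs) {
    if (r$chrom != iso$chrom || r$strand != iso$strand) next
    ci <- iso_chain(iso); cr <- iso_chain(r)
    if (ci != "" && ci == cr) hits <- c(hits, r$transcript_id)
    if (ci == "" && cr == "") {
      ov <- min(iso$ends[1], r$ends[1]) - max(iso$starts[1], r$starts[1])
      if (ov > 0 && ov / (iso$ends[1] - iso$starts[1]) >= 0.5 &&
          ov / (r$ends[1] - r$starts[1]) >= 0.5)
        hits <- c(hits, r$transcript_id)
    }
  }
  if (length(hits) == 0) NULL else sort(hits)
}

# small two-gene reference used across filtering tests:
#  REFA.t1 (+, 3 exons) and REFB.t1 (-, 2 exons) on one contig
fixture_reference <- function() {
  list(
    transcript_model("REFA.t1", "REFA", "chrFix", "+",
                     starts = c(1000L, 2000L, 3000L),
                     ends = c(1200L, 2200L, 3200L)),
    transcript_model("REFB.t1", "REFB", "chrFix", "-",
                     starts = c(10000L, 12000L),
                     ends = c(10500L, 12500L)))
}

# a read exactly matching a transcript model, optionally polyadenylated
read_from_tx <- function(tx, read_id, polya = "polyadenylated") {
  aligned_read(read_id, tx$chrom, tx$strand, tx$starts, tx$ends,
               polya = polya)
}

# random exon-block read on a toy contig (for property tests)
random_read <- function(id, chrom = "chrR", strand = NULL) {
  n <- sample(1:4, 1)
  if (is.null(strand)) strand <- sample(c("+", "-"), 1)
  pos <- sample(0:5000, 1)
  starts <- integer(n); ends <- integer(n)
  for (i in seq_len(n)) {
    starts[i] <- pos
    ends[i] <- pos + sample(20:200, 1)
    pos <- ends[i] + sample(30:400, 1)
  }
  aligned_read(id, chrom, strand, starts, ends)
}

# zero-noise simulator configuration (the identity regime)
noise_free_config <- function(n_genes = 10L, n_reads = 2000L, seed = 7L) {
  sim_config(n_genes = n_genes, n_reads = n_reads,
             p_jitter = 0, jitter_max = 0L, p_truncate_5p = 0,
             p_polya_given_full = 1, p_polya_given_truncated = 0,
             p_polya_missing = 0, sigma_start = 0, sigma_end = 0,
             seed = seed)
}
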