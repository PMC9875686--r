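#' Simulation configuration
#'
#' Defaults emulate a realistic nanopore direct RNA-seq run: a few dozen
#' multi-isoform genes, log-normal expression, multinomial read sampling,
#' 5'-biased truncation of about a fifth of the reads (RNA fragmentation and
#' pore blocking lose 5' ends; the motor sequences 3' to 5'), moderate
#' splice-site jitter from basecalling/alignment error, small Gaussian
#' terminal noise, and imperfect poly(A) calling with some dropout.
#'
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Integer range `c(min, max)`.
#' @param exons_per_isoform Integer range for the gene's exon skeleton.
#' @param exon_len,intron_len Length ranges in bp.
#' @param expr_meanlog,expr_sdlog Log-normal expression parameters.
#' @param n_reads Total reads to simulate.
#' @param p_jitter Per-junction probability of splice-site displacement.
#' @param jitter_max Maximum displacement, bp (uniform on +/- jitter_max,
#'   never crossing the midpoint of a flanking exon).
#' @param p_truncate_5p Per-read probability of 5' truncation.
#' @param trunc_mean Mean of the exponential truncation length, bp.
#' @param p_polya_given_full,p_polya_given_truncated Probability that a
#'   full-length / truncated read gets a confirmed poly(A) call.
#' @param p_polya_missing Probability a read is absent from the poly(A)
#'   table entirely (call dropout; such reads are `unknown`).
#' @param sigma_start,sigma_end Gaussian terminal noise SD, bp.
#' @param truncate_3p Also truncate from the 3' end (degraded-sample
#'   regime); off by default.
#' @param seed Seed; a fixed seed yields byte-identical outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 20L, isoforms_per_gene = c(2L, 4L),
                       exons_per_isoform = c(3L, 9L),
                       exon_len = c(100L, 300L), intron_len = c(200L, 2000L),
                       expr_meanlog = 1, expr_sdlog = 1.5,
                       n_reads = 5000L,
                       p_jitter = 0.15, jitter_max = 30L,
                       p_truncate_5p = 0.2, trunc_mean = 800,
                       p_polya_given_full = 0.9,
                       p_polya_given_truncated = 0.3,
                       p_polya_missing = 0.05,
                       sigma_start = 5, sigma_end = 5,
                       truncate_3p = FALSE, seed = 42L) {
  cfg <- as.list(environment())
  probs <- c(cfg$p_jitter, cfg$p_truncate_5p, cfg$p_polya_given_full,
             cfg$p_polya_given_truncated, cfg$p_polya_missing)
  stopifnot(all(probs >= 0 & probs <= 1),
            all(cfg$exon_len > 0), all(cfg$intron_len > 0),
            cfg$n_genes >= 1, cfg$n_reads >= 1)
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic multi-isoform annotation
#'
#' Genes are placed without overlap on two synthetic contigs, alternating
#' strands. Each gene gets an exon skeleton (the "master" isoform); further
#' isoforms skip one internal exon each (from the third exon on, so all
#' isoforms of a gene share the first junction and every splice site stays
#' annotated). Distinct same-kind splice sites are separated by at least an
#' exon plus an intron, so jitter up to half the minimum exon length can
#' always be corrected back to the true site.
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to the config's).
#' @param gtf_path Optional path; when given the annotation is written as
#'   GTF.
#' @return List of [transcript_model()] objects (`truth`), invisibly
#'   accompanied by the file when `gtf_path` is given.
#' @export
generate_annotation <- function(config = sim_config(), seed = config$seed,
                                gtf_path = NULL) {
  set.seed(seed)
  rint <- function(rng) if (rng[1] == rng[2]) rng[1] else
    sample(rng[1]:rng[2], 1L)
  k_iso <- vapply(seq_len(config$n_genes), function(i)
    rint(config$isoforms_per_gene), integer(1))
  # an isoform skipping one internal exon (>= 3rd) needs E >= k + 2 exons
  need_min <- pmax(k_iso + 2L, config$exons_per_isoform[1])
  if (any(need_min > config$exons_per_isoform[2]))
    stop("infeasible ranges: isoforms_per_gene needs exons_per_isoform max ",
         "of at least max(isoforms_per_gene) + 2")
  contigs <- c("chrS1", "chrS2")
  offsets <- stats::setNames(rep(10000L, length(contigs)), contigs)
  out <- list()
  for (g in seq_len(config$n_genes)) {
    contig <- contigs[(g - 1L) %% length(contigs) + 1L]
    strand <- if (g %% 2L == 0L) "-" else "+"
    n_exons <- rint(c(need_min[g], config$exons_per_isoform[2]))
    elens <- vapply(seq_len(n_exons), function(i) rint(config$exon_len),
                    integer(1))
    ilens <- if (n_exons > 1L)
      vapply(seq_len(n_exons - 1L), function(i) rint(config$intron_len),
             integer(1)) else integer(0)
    starts <- integer(n_exons); ends <- integer(n_exons)
    pos <- offsets[[contig]]
    for (e in seq_len(n_exons)) {
      starts[e] <- pos; ends[e] <- pos + elens[e]
      pos <- ends[e] + if (e < n_exons) ilens[e] else 0L
    }
    offsets[[contig]] <- pos + 10000L  # intergenic gap
    gene_id <- sprintf("SIMG_%03d", g)
    out[[length(out) + 1L]] <- transcript_model(
      sprintf("%s.t1", gene_id), gene_id, contig, strand, starts, ends)
    if (k_iso[g] > 1L) {
      skippable <- 3:(n_exons - 1L)
      skip <- skippable[seq_len(k_iso[g] - 1L)]
      for (v in seq_along(skip)) {
        keep <- setdiff(seq_len(n_exons), skip[v])
        out[[length(out) + 1L]] <- transcript_model(
          sprintf("%s.t%d", gene_id, v + 1L), gene_id, contig, strand,
          starts[keep], ends[keep])
      }
    }
  }
  if (!is.null(gtf_path)) write_isoform_gtf(out, gtf_path)
  out
}

#' Assign log-normal expression to transcripts
#'
#' TPM values are drawn log-normal(`expr_meanlog`, `expr_sdlog`) and
#' renormalized to sum to 1e6. With `expr_sdlog = 0` all transcripts are
#' equally expressed.
#'
#' @param transcripts List of [transcript_model()].
#' @param config A [sim_config()].
#' @param seed Seed.
#' @return data.frame with `transcript_id`, `tpm`.
#' @export
assign_expression <- function(transcripts, config = sim_config(),
                              seed = config$seed) {
  set.seed(seed + 1L)
  n <- length(transcripts)
  raw <- stats::rlnorm(n, meanlog = config$expr_meanlog,
                       sdlog = config$expr_sdlog)
  data.frame(
    transcript_id = vapply(transcripts, function(tx) tx$transcript_id,
                           character(1)),
    tpm = raw / sum(raw) * 1e6,
    stringsAsFactors = FALSE)
}

# remove `len` bases from the transcript's 5' end, respecting exon structure;
# keeps at least `keep_min` transcribed bases
truncate_5p <- function(starts, ends, strand, len, keep_min = 20L) {
  total <- sum(ends - starts)
  len <- min(len, total - keep_min)
  if (len <= 0L) return(list(starts = starts, ends = ends))
  if (strand == "+") {
    while (len >= ends[1L] - starts[1L] && length(starts) > 1L) {
      len <- len - (ends[1L] - starts[1L])
      starts <- starts[-1L]; ends <- ends[-1L]
    }
    starts[1L] <- starts[1L] + max(0L, min(len, ends[1L] - starts[1L] - 1L))
  } else {
    n <- length(starts)
    while (len >= ends[n] - starts[n] && n > 1L) {
      len <- len - (ends[n] - starts[n])
      starts <- starts[-n]; ends <- ends[-n]; n <- n - 1L
    }
    ends[n] <- ends[n] - max(0L, min(len, ends[n] - starts[n] - 1L))
  }
  list(starts = starts, ends = ends)
}

#' Simulate spliced long reads from an annotation
#'
#' Reads are sampled multinomially by TPM. Each read starts as its source
#' transcript's exon structure, then: with probability `p_truncate_5p` an
#' exponential length is removed from the 5' end (whole exons may be lost,
#' changing the intron chain); terminal positions get Gaussian noise; each
#' junction is displaced with probability `p_jitter` (donor and acceptor
#' shifted independently, uniform within +/- `jitter_max`, clamped so no
#' exon shrinks past its midpoint and no intron closes); the poly(A) flag is
#' drawn from the truncation-conditional probabilities, and a fraction of
#' reads drop out of the poly(A) table entirely.
#'
#' @param transcripts Truth annotation ([generate_annotation()]).
#' @param expression data.frame from [assign_expression()].
#' @param config A [sim_config()].
#' @param seed Seed.
#' @param out_dir Optional directory; when given, writes `reads.sam`,
#'   `polya.tsv`, `truth.gtf`, `expression.tsv`, `cage.bed`,
#'   `polya_clusters.bed`.
#' @return List: `reads` (list of [aligned_read()]), `polya` (a
#'   `polya_table`), `truth` (per-read data.frame: read_id, transcript_id,
#'   truncated, polya_state, n_jittered_sites), `cage` and `polya_clusters`
#'   (`peak_set`s over the true TSS/TES), and the file paths when `out_dir`
#'   is given.
#' @export
simulate_reads <- function(transcripts, expression, config = sim_config(),
                           seed = config$seed, out_dir = NULL) {
  set.seed(seed + 2L)
  n_tx <- length(transcripts)
  tpm <- stats::setNames(expression$tpm, expression$transcript_id)
  ids <- vapply(transcripts, function(tx) tx$transcript_id, character(1))
  counts <- as.integer(stats::rmultinom(1L, config$n_reads,
                                        prob = tpm[ids]))
  reads <- vector("list", config$n_reads)
  truth <- vector("list", config$n_reads)
  polya_rows <- vector("list", config$n_reads)
  ri <- 0L
  for (t in seq_len(n_tx)) {
    tx <- transcripts[[t]]
    if (counts[t] == 0L) next
    for (k in seq_len(counts[t])) {
      ri <- ri + 1L
      starts <- tx$starts; ends <- tx$ends
      truncated <- stats::runif(1) < config$p_truncate_5p
      if (truncated) {
        tl <- as.integer(ceiling(stats::rexp(1, 1 / config$trunc_mean)))
        tr <- truncate_5p(starts, ends, tx$strand, tl)
        starts <- tr$starts; ends <- tr$ends
      }
      if (config$truncate_3p && stats::runif(1) < config$p_truncate_5p) {
        tr <- truncate_5p(starts, ends,
                          if (tx$strand == "+") "-" else "+",
                          as.integer(ceiling(stats::rexp(1, 1 / config$trunc_mean))))
        starts <- tr$starts; ends <- tr$ends
      }
      # terminal Gaussian noise, clamped inside the terminal exons
      if (config$sigma_start > 0 || config$sigma_end > 0) {
        d5 <- as.integer(round(stats::rnorm(1, 0, config$sigma_start)))
        d3 <- as.integer(round(stats::rnorm(1, 0, config$sigma_end)))
        n <- length(starts)
        if (tx$strand == "+") {
          starts[1L] <- max(0L, min(starts[1L] + d5, ends[1L] - 1L))
          ends[n] <- max(starts[n] + 1L, ends[n] + d3)
        } else {
          ends[n] <- max(starts[n] + 1L, ends[n] + d5)
          starts[1L] <- max(0L, min(starts[1L] + d3, ends[1L] - 1L))
        }
      }
      # junction jitter
      n_jit <- 0L
      n <- length(starts)
      if (n > 1L && config$p_jitter > 0 && config$jitter_max > 0) {
        jdraw <- function(lo, hi) {
          lo <- max(lo, -config$jitter_max); hi <- min(hi, config$jitter_max)
          if (hi < lo) return(0L)
          sample(lo:hi, 1L)
        }
        for (j in seq_len(n - 1L)) {
          if (stats::runif(1) >= config$p_jitter) next
          half_l <- (ends[j] - starts[j]) %/% 2L
          half_r <- (ends[j + 1L] - starts[j + 1L]) %/% 2L
          # donor side: left into exon j (up to its midpoint), right into
          # the intron (keep >= 1 bp)
          dd <- jdraw(-(half_l - 1L), starts[j + 1L] - ends[j] - 1L)
          if (dd != 0L && ends[j] + dd > starts[j] &&
              ends[j] + dd < starts[j + 1L]) {
            ends[j] <- ends[j] + dd; n_jit <- n_jit + 1L
          }
          da <- jdraw(-(starts[j + 1L] - ends[j] - 1L), half_r - 1L)
          if (da != 0L && starts[j + 1L] + da > ends[j] &&
              starts[j + 1L] + da < ends[j + 1L]) {
            starts[j + 1L] <- starts[j + 1L] + da; n_jit <- n_jit + 1L
          }
        }
      }
      p_pa <- if (truncated) config$p_polya_given_truncated else
        config$p_polya_given_full
      has_polya <- stats::runif(1) < p_pa
      missing_call <- stats::runif(1) < config$p_polya_missing
      read_id <- sprintf("simread_%06d", ri)
      polya_state <- if (missing_call) "unknown" else
        if (has_polya) "polyadenylated" else "not_polyadenylated"
      reads[[ri]] <- aligned_read(read_id, tx$chrom, tx$strand,
                                  starts, ends, polya = polya_state)
      truth[[ri]] <- data.frame(
        read_id = read_id, transcript_id = tx$transcript_id,
        truncated = truncated, polya_state = polya_state,
        n_jittered_sites = n_jit, stringsAsFactors = FALSE)
      if (!missing_call)
        polya_rows[[ri]] <- data.frame(
          readname = read_id,
          qc_tag = if (has_polya) "PASS" else "NOREGION",
          stringsAsFactors = FALSE)
    }
  }
  reads <- reads[seq_len(ri)]
  truth <- do.call(rbind, truth[seq_len(ri)])
  polya_df <- do.call(rbind, polya_rows[!vapply(polya_rows, is.null,
                                                logical(1))])
  if (is.null(polya_df))
    polya_df <- data.frame(readname = character(0), qc_tag = character(0))
  polya <- structure(
    as.list(stats::setNames(
      ifelse(polya_df$qc_tag == "PASS", "polyadenylated",
             "not_polyadenylated"),
      polya_df$readname)), class = "polya_table")
  # truth peaks: +/- 5 bp around every annotated TSS/TES
  mk_peaks <- function(side, label) {
    pos <- unique(t(vapply(transcripts, function(tx) c(
      chrom = tx$chrom, strand = tx$strand,
      p = as.character(if (side == "tss")
        five_prime_end(tx$strand, tx$starts, tx$ends)
        else three_prime_end(tx$strand, tx$starts, tx$ends))),
      character(3))))
    df <- data.frame(chrom = pos[, "chrom"],
                     start = pmax(0L, as.integer(pos[, "p"]) - 5L),
                     end = as.integer(pos[, "p"]) + 5L,
                     strand = pos[, "strand"], stringsAsFactors = FALSE)
    peak_set(df[order(df$chrom, df$start), , drop = FALSE], label)
  }
  cage <- mk_peaks("tss", "cage")
  pac <- mk_peaks("tes", "polya_cluster")
  res <- list(reads = reads, polya = polya, truth = truth,
              cage = cage, polya_clusters = pac)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    res$sam_path <- file.path(out_dir, "reads.sam")
    write_sam(reads, res$sam_path)
    res$polya_path <- file.path(out_dir, "polya.tsv")
    utils::write.table(polya_df, res$polya_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res$gtf_path <- file.path(out_dir, "truth.gtf")
    write_isoform_gtf(transcripts, res$gtf_path)
    res$expression_path <- file.path(out_dir, "expression.tsv")
    utils::write.table(expression, res$expression_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$cage_path <- file.path(out_dir, "cage.bed")
    write_bed(cage, res$cage_path)
    res$polya_clusters_path <- file.path(out_dir, "polya_clusters.bed")
    write_bed(pac, res$polya_clusters_path)
  }
  res
}

# minimal SAM writer for simulated alignments: coordinate-sorted records,
# CIGAR rebuilt from exon blocks, placeholder bases, ts:A:+ strand tag
write_sam <- function(reads, path) {
  chroms <- sort(unique(vapply(reads, function(r) r$chrom, character(1))))
  maxend <- vapply(chroms, function(ch)
    max(vapply(reads[vapply(reads, function(r) r$chrom == ch, logical(1))],
               function(r) r$ends[length(r$ends)], integer(1))), integer(1))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", chroms, maxend + 10000L), con)
  ord <- order(vapply(reads, function(r) r$chrom, character(1)),
               vapply(reads, function(r) r$starts[1L], integer(1)))
  for (r in reads[ord]) {
    n <- length(r$starts)
    widths <- r$ends - r$starts
    cig <- paste0(widths[1L], "M")
    if (n > 1L) {
      gaps <- r$starts[-1L] - r$ends[-n]
      cig <- paste0(cig, paste0(gaps, "N", widths[-1L], "M", collapse = ""))
    }
    flag <- if (r$strand == "+") 0L else 16L
    seq <- strrep("A", sum(widths))
    writeLines(paste(r$read_id, flag, r$chrom, r$starts[1L] + 1L, r$mapq,
                     cig, "*", 0L, 0L, seq, "*", "ts:A:+", sep = "\t"), con)
  }
  invisible(path)
}

write_bed <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end,
                   name = sprintf("peak_%d", seq_len(nrow(peaks))),
                   score = 0L, strand = peaks$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
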