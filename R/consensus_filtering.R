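#' Pipeline configuration
#'
#' Houses every tunable threshold of the isoform-calling pipeline. The
#' junction-correction bound (`max_shift = 40` bp) and the novel-junction
#' read-support threshold (`min_sj_reads = 2`) are the method's stated
#' defaults; `min_polya_reads = 1` is the weakest reading of "sufficient
#' polyadenylation events" and `tss_window = 50` bp is the filtering window
#' for TSS evidence, kept separate from the +/- 25 bp evaluation window
#' (`eval_window`) used when scoring against orthogonal peak data.
#'
#' @param max_shift Junction correction bound, bp.
#' @param min_sj_reads Minimum read support for a novel splice junction.
#' @param min_polya_reads Minimum polyadenylated reads for a novel chain.
#' @param tss_window TSS filter window, bp.
#' @param eval_window Evaluation window for orthogonal TSS/TES support, bp.
#' @param min_gmm_reads Minimum cluster size for the mixture boundary fit.
#' @param max_components Maximum mixture components tried.
#' @param min_component_weight Minimum weight for reported minor components.
#' @param seed Random seed threaded through every stochastic step.
#' @param polya_pass_tag QC value counted as a confirmed poly(A) tail.
#' @param min_mapq Minimum mapping quality at alignment parsing.
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_shift = 40L, min_sj_reads = 2L,
                          min_polya_reads = 1L, tss_window = 50L,
                          eval_window = 25L, min_gmm_reads = 3L,
                          max_components = 3L, min_component_weight = 0.2,
                          seed = 42L, polya_pass_tag = "PASS",
                          min_mapq = 1L) {
  cfg <- list(max_shift = max_shift, min_sj_reads = min_sj_reads,
              min_polya_reads = min_polya_reads, tss_window = tss_window,
              eval_window = eval_window, min_gmm_reads = min_gmm_reads,
              max_components = max_components,
              min_component_weight = min_component_weight, seed = seed,
              polya_pass_tag = polya_pass_tag, min_mapq = min_mapq)
  stopifnot(all(vapply(cfg[c("max_shift", "min_sj_reads", "min_polya_reads",
                             "tss_window", "eval_window", "min_gmm_reads")],
                       function(x) x >= 0, logical(1))))
  structure(cfg, class = "filter_config")
}

#' Count read support per splice junction
#'
#' Each junction is counted once per read containing it, over the full
#' (pre-collapse) corrected read set.
#'
#' @param reads List of corrected [aligned_read()].
#' @return Named integer vector: junction key -> read count.
#' @export
count_junction_support <- function(reads) {
  keys <- unlist(lapply(reads, function(r) {
    ic <- intron_coords(r$starts, r$ends)
    junction_keys(r$chrom, r$strand, ic$starts, ic$ends)
  }))
  if (is.null(keys) || length(keys) == 0L)
    return(stats::setNames(integer(0), character(0)))
  tab <- table(keys)
  stats::setNames(as.integer(tab), names(tab))
}

cluster_junction_keys <- function(cl)
  junction_keys(cl$chrom, cl$strand, cl$istarts, cl$iends)

cluster_is_novel_chain <- function(cl, index) {
  if (cl$single_exon) return(TRUE)
  is.null(index$chain_lookup[[cl$chain_key]])
}

#' Filter 1: drop clusters carrying unsupported novel junctions
#'
#' A cluster is discarded iff one of its junctions is absent from the
#' annotated junction set and is supported by fewer than `min_sj_reads`
#' reads overall; annotated junctions are exempt regardless of support.
#' Single-exon clusters (no junctions) pass trivially.
#'
#' @param clusters List of `read_cluster`.
#' @param index A [build_reference_index()] result.
#' @param support Result of [count_junction_support()] over all reads.
#' @param min_sj_reads Support threshold for novel junctions (default 2).
#' @return `list(kept, dropped)`.
#' @export
filter_novel_junctions <- function(clusters, index, support,
                                   min_sj_reads = 2L) {
  pass <- vapply(clusters, function(cl) {
    jk <- cluster_junction_keys(cl)
    if (length(jk) == 0L) return(TRUE)
    novel <- !is_annotated_junction(index, jk)
    if (!any(novel)) return(TRUE)
    cnt <- support[jk[novel]]
    cnt[is.na(cnt)] <- 0L
    all(cnt >= min_sj_reads)
  }, logical(1))
  list(kept = clusters[pass], dropped = clusters[!pass])
}

#' Filter 2: drop novel chains without polyadenylation evidence
#'
#' A cluster whose intron chain is absent from the reference (including
#' every single-exon cluster) is discarded iff fewer than `min_polya_reads`
#' of its members carry a confirmed poly(A) tail. Clusters matching an
#' annotated chain are exempt. Reads with unknown poly(A) status count as
#' not polyadenylated.
#'
#' @inheritParams filter_novel_junctions
#' @param min_polya_reads Minimum polyadenylated members (default 1).
#' @return `list(kept, dropped)`.
#' @export
filter_polya <- function(clusters, index, min_polya_reads = 1L) {
  pass <- vapply(clusters, function(cl) {
    if (!cluster_is_novel_chain(cl, index)) return(TRUE)
    cl$n_polya >= min_polya_reads
  }, logical(1))
  list(kept = clusters[pass], dropped = clusters[!pass])
}

#' Filter 3: drop clusters whose TSS has no annotation or CAGE support
#'
#' A cluster is kept iff its primary TSS lies within `tss_window` bp of an
#' annotated TSS on the same chromosome and strand, or inside a CAGE peak
#' extended by `tss_window`. The evidence source is recorded on the cluster
#' (`tss_evidence`: `"annotated"`, `"cage"` or `"none"`). When no peak set
#' is supplied only annotated TSSs count.
#'
#' @inheritParams filter_novel_junctions
#' @param cage Optional `peak_set` of CAGE/SAGE peaks.
#' @param tss_window Window in bp (default 50).
#' @return `list(kept, dropped)`; kept clusters carry `tss_evidence`.
#' @export
filter_tss <- function(clusters, index, cage = NULL, tss_window = 50L) {
  annotated <- logical(length(clusters))
  evidence <- character(length(clusters))
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    if (is.null(cl$boundaries))
      stop("filter_tss requires clusters with boundary estimates")
    tss <- cl$boundaries$tss$primary
    if (nearest_tss_distance(index, cl$chrom, cl$strand, tss) <= tss_window) {
      annotated[i] <- TRUE; evidence[i] <- "annotated"
    } else if (!is.null(cage) &&
               point_in_peaks(cage, cl$chrom, tss, window = tss_window,
                              strand = cl$strand)) {
      annotated[i] <- TRUE; evidence[i] <- "cage"
    } else {
      evidence[i] <- "none"
    }
    clusters[[i]]$tss_evidence <- evidence[i]
  }
  list(kept = clusters[annotated], dropped = clusters[!annotated])
}

# gene id by maximal exonic overlap with the reference; novel loci get a
# NOVELG_ counter shared by mutually overlapping novel isoforms.
assign_gene_ids <- function(isoforms, index) {
  ref <- index$transcripts
  novel_spans <- list()  # per chrom|strand: matrix of (start, end, gene_no)
  novel_counter <- 0L
  for (i in seq_along(isoforms)) {
    iso <- isoforms[[i]]
    best_gene <- NA_character_; best_ov <- 0L
    for (tx in ref) {
      if (tx$chrom != iso$chrom || tx$strand != iso$strand) next
      ov <- 0L
      for (j in seq_along(tx$starts)) {
        ov <- ov + sum(pmax(0L, pmin(iso$ends, tx$ends[j]) -
                              pmax(iso$starts, tx$starts[j])))
      }
      if (ov > best_ov) { best_ov <- ov; best_gene <- tx$gene_id }
    }
    if (!is.na(best_gene)) {
      isoforms[[i]]$gene_id <- best_gene
      next
    }
    key <- paste0(iso$chrom, "|", iso$strand)
    span <- c(iso$starts[1L], iso$ends[length(iso$ends)])
    assigned <- NA_integer_
    for (sp in novel_spans[[key]]) {
      if (span[1L] < sp[2L] && sp[1L] < span[2L]) { assigned <- sp[3L]; break }
    }
    if (is.na(assigned)) {
      novel_counter <- novel_counter + 1L
      assigned <- novel_counter
    }
    novel_spans[[key]] <- c(novel_spans[[key]], list(c(span, assigned)))
    isoforms[[i]]$gene_id <- sprintf("NOVELG_%d", assigned)
  }
  isoforms
}

cluster_to_isoform <- function(cl, index, id) {
  b <- cl$boundaries
  structure(list(
    transcript_id = id, gene_id = NA_character_,
    chrom = cl$chrom, strand = cl$strand,
    starts = b$starts, ends = b$ends,
    istarts = cl$istarts, iends = cl$iends,
    chain_key = cl$chain_key,
    n_reads = cl$n_reads, n_polya = cl$n_polya,
    is_novel_chain = cluster_is_novel_chain(cl, index),
    single_exon = cl$single_exon,
    tss_evidence = cl$tss_evidence %||% "none",
    tss = b$tss, tes = b$tes,
    filter_trace = cl$filter_trace,
    source = "assembled"), class = "isoform_call")
}

#' Call high-consensus full-length isoforms from long-read alignments
#'
#' End-to-end pipeline: parse alignments, build the reference index, correct
#' splice junctions against the annotation (within `max_shift` bp), collapse
#' reads by intron chain (single-exon reads by reciprocal overlap), estimate
#' TSS/TES per cluster with a Gaussian mixture, then apply the three-step
#' filter — (1) novel junctions need `min_sj_reads` supporting reads,
#' (2) novel chains need `min_polya_reads` polyadenylated reads,
#' (3) the TSS needs annotation or CAGE support within `tss_window` bp —
#' and emit the survivors as transcript models.
#'
#' @param bam SAM/BAM path, or an already-parsed list of [aligned_read()].
#' @param gtf Reference GTF path, or a list of [transcript_model()].
#' @param polya Poly(A) TSV path (nanopolish dialect), a `polya_table`, or
#'   `NULL`.
#' @param cage Optional CAGE/SAGE BED path or `peak_set`.
#' @param config A [filter_config()].
#' @param out_gtf Optional path; when given the emitted isoforms are written
#'   with [write_isoform_gtf()].
#' @param verbose Log per-stage counts to stderr.
#' @return `list(isoforms, clusters, dropped, summary)`; `dropped` holds the
#'   clusters removed at each filter step, `summary` the per-stage counts.
#' @export
call_isoforms <- function(bam, gtf, polya = NULL, cage = NULL,
                          config = filter_config(), out_gtf = NULL,
                          verbose = FALSE) {
  log_msg <- function(...) if (verbose) message("[isoforge] ", ...)
  if (is.character(polya))
    polya <- parse_polya_table(polya, pass_tag = config$polya_pass_tag)
  reads <- if (is.character(bam))
    parse_alignments(bam, min_mapq = config$min_mapq, polya = polya)
  else if (!is.null(polya)) attach_polya(bam, polya) else bam
  transcripts <- if (is.character(gtf)) parse_annotation(gtf) else gtf
  if (is.character(cage)) cage <- parse_peaks(cage, label = "cage")
  index <- build_reference_index(transcripts)
  log_msg(length(reads), " reads, ", length(transcripts),
          " reference transcripts")

  corr <- correct_all(reads, index, max_shift = config$max_shift)
  log_msg(nrow(corr$records), " junction sides corrected")

  spliced <- Filter(function(r) length(r$starts) > 1L, corr$reads)
  unspliced <- Filter(function(r) length(r$starts) == 1L, corr$reads)
  support <- count_junction_support(spliced)
  clusters <- c(group_by_intron_chain(spliced),
                cluster_single_exon(unspliced))
  log_msg(length(clusters), " clusters (",
          sum(vapply(clusters, function(cl) cl$single_exon, logical(1))),
          " single-exon)")

  for (i in seq_along(clusters))
    clusters[[i]]$boundaries <- estimate_boundaries(clusters[[i]], config)

  f1 <- filter_novel_junctions(clusters, index, support,
                               min_sj_reads = config$min_sj_reads)
  log_msg("filter 1 (novel junction support): ", length(f1$kept), " kept, ",
          length(f1$dropped), " dropped")
  f2 <- filter_polya(f1$kept, index,
                     min_polya_reads = config$min_polya_reads)
  log_msg("filter 2 (poly(A) evidence): ", length(f2$kept), " kept, ",
          length(f2$dropped), " dropped")
  f3 <- filter_tss(f2$kept, index, cage = cage,
                   tss_window = config$tss_window)
  log_msg("filter 3 (TSS support): ", length(f3$kept), " kept, ",
          length(f3$dropped), " dropped")

  kept <- f3$kept
  for (i in seq_along(kept))
    kept[[i]]$filter_trace <- c(junction_support = TRUE, polya = TRUE,
                                tss = TRUE)
  isoforms <- vector("list", length(kept))
  for (i in seq_along(kept))
    isoforms[[i]] <- cluster_to_isoform(kept[[i]], index,
                                        sprintf("ISOT_%06d", i))
  isoforms <- assign_gene_ids(isoforms, index)
  # every emitted isoform must satisfy all three predicates; re-check
  stopifnot(all(vapply(isoforms, function(iso)
    iso$tss_evidence != "none" &&
      (!iso$is_novel_chain || iso$n_polya >= config$min_polya_reads),
    logical(1))))
  if (!is.null(out_gtf)) {
    if (length(isoforms) == 0L)
      warning("no isoforms survived filtering; writing empty GTF")
    write_isoform_gtf(isoforms, out_gtf)
  }
  summary <- list(
    n_reads = length(reads), n_clusters = length(clusters),
    dropped_junction = length(f1$dropped), dropped_polya = length(f2$dropped),
    dropped_tss = length(f3$dropped), n_isoforms = length(isoforms))
  list(isoforms = isoforms, clusters = clusters,
       dropped = list(junction = f1$dropped, polya = f2$dropped,
                      tss = f3$dropped),
       summary = summary)
}

#' Merge fraction-specific assemblies into a nonredundant isoform set
#'
#' Spliced isoforms with identical (chrom, strand, intron chain) are merged:
#' the representative boundaries come from the member with the most
#' supporting reads, and read/poly(A) counts are summed. Single-exon
#' isoforms are merged by single-linkage reciprocal overlap >= 0.5.
#'
#' @param assemblies List of isoform-call lists (one per assembly).
#' @return A single nonredundant list of isoform calls.
#' @export
merge_assemblies <- function(assemblies) {
  all_iso <- do.call(c, assemblies)
  if (length(all_iso) == 0L) return(list())
  spliced <- Filter(function(x) length(x$istarts) > 0L, all_iso)
  single <- Filter(function(x) length(x$istarts) == 0L, all_iso)
  out <- list()
  if (length(spliced)) {
    keys <- vapply(spliced, function(x) x$chain_key, character(1))
    for (ii in split(seq_along(spliced), keys)) {
      grp <- spliced[ii]
      out[[length(out) + 1L]] <- merge_isoform_group(grp)
    }
  }
  if (length(single)) {
    bychrom <- split(seq_along(single), vapply(single, function(x)
      paste0(x$chrom, "|", x$strand), character(1)))
    for (ii in bychrom) {
      grp <- single[ii]; n <- length(grp)
      parent <- seq_len(n)
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      for (a in seq_len(n)) for (b in seq_len(n)) {
        if (a >= b) next
        if (reciprocal_overlap(grp[[a]]$starts[1L], grp[[a]]$ends[1L],
                               grp[[b]]$starts[1L], grp[[b]]$ends[1L]) >= 0.5) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[min(ra, rb)] <- max(ra, rb)
        }
      }
      roots <- vapply(seq_len(n), find, integer(1))
      for (mm in split(seq_len(n), roots))
        out[[length(out) + 1L]] <- merge_isoform_group(grp[mm])
    }
  }
  for (i in seq_along(out)) out[[i]]$transcript_id <- sprintf("ISOT_%06d", i)
  out
}

merge_isoform_group <- function(grp) {
  rep_iso <- grp[[which.max(vapply(grp, function(x) x$n_reads, numeric(1)))]]
  rep_iso$n_reads <- sum(vapply(grp, function(x) x$n_reads, numeric(1)))
  rep_iso$n_polya <- sum(vapply(grp, function(x) x$n_polya, numeric(1)))
  rep_iso
}
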