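#' Match an assembled isoform to the reference
#'
#' A spliced isoform matches a reference transcript with the identical intron
#' chain (chrom, strand, exact junction coordinates); terminal TSS/TES
#' positions are not compared, mirroring the gffcompare-style `=` class
#' code. A single-exon isoform matches a single-exon reference transcript
#' with reciprocal overlap >= 0.5.
#'
#' @param isoform An isoform call or [transcript_model()].
#' @param index A [build_reference_index()] result.
#' @return Character vector of matching transcript ids (possibly several,
#'   sorted), or `NULL` when nothing matches.
#' @export
match_isoform <- function(isoform, index) {
  ic <- isoform_chain(isoform)
  if (length(ic$starts) > 0L) {
    key <- chain_key(isoform$chrom, isoform$strand, ic$starts, ic$ends)
    hits <- index$chain_lookup[[key]]
    if (is.null(hits)) return(NULL)
    return(sort(hits))
  }
  hits <- character(0)
  for (tx in index$transcripts) {
    if (length(tx$starts) != 1L || tx$chrom != isoform$chrom ||
        tx$strand != isoform$strand) next
    if (reciprocal_overlap(isoform$starts[1L], isoform$ends[1L],
                           tx$starts[1L], tx$ends[1L]) >= 0.5)
      hits <- c(hits, tx$transcript_id)
  }
  if (length(hits) == 0L) NULL else sort(hits)
}

isoform_chain <- function(iso) {
  if (!is.null(iso$istarts)) list(starts = iso$istarts, ends = iso$iends)
  else intron_coords(iso$starts, iso$ends)
}

#' Precision and recall of an assembly against the reference
#'
#' TP is the number of assembled isoforms matched to a reference transcript
#' ([match_isoform()]), each reference consumable at most once (greedy, in
#' sorted transcript-id order for determinism); FP the assembled isoforms
#' without a match; FN the reference transcripts matched by nothing.
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN); undefined ratios (empty
#' assembly or reference) are reported as NaN.
#'
#' @param assembly List of isoform calls.
#' @param index A [build_reference_index()] result.
#' @return List with `TP`, `FP`, `FN`, `precision`, `recall`,
#'   `matched_ref_ids`.
#' @export
precision_recall <- function(assembly, index) {
  n_ref <- length(index$transcripts)
  ord <- order(vapply(assembly, function(x)
    x$transcript_id %||% "", character(1)))
  consumed <- character(0)
  tp <- 0L
  for (iso in assembly[ord]) {
    hits <- match_isoform(iso, index)
    hits <- setdiff(hits, consumed)
    if (length(hits) > 0L) {
      consumed <- c(consumed, hits[1L])
      tp <- tp + 1L
    }
  }
  fp <- length(assembly) - tp
  fn <- n_ref - length(consumed)
  list(TP = tp, FP = fp, FN = fn,
       precision = if (length(assembly) == 0L) NaN else tp / (tp + fp),
       recall = if (n_ref == 0L) NaN else tp / (tp + fn),
       matched_ref_ids = consumed)
}

#' Fraction of isoform termini supported by orthogonal peak data
#'
#' An isoform's 5' (TSS) or 3' (TES) terminus is supported when it lies
#' within any peak extended by +/- `window` bp (the evaluation convention
#' for CAGE/SAGE peaks and poly(A) clusters).
#'
#' @param isoforms List of isoform calls.
#' @param peaks A `peak_set`.
#' @param side `"tss"` or `"tes"`.
#' @param window Extension in bp (default 25).
#' @return Supported fraction; NaN for an empty isoform set.
#' @export
boundary_support_rate <- function(isoforms, peaks, side = c("tss", "tes"),
                                  window = 25L) {
  side <- match.arg(side)
  if (length(isoforms) == 0L) return(NaN)
  supported <- vapply(isoforms, function(iso) {
    pos <- if (side == "tss")
      five_prime_end(iso$strand, iso$starts, iso$ends)
    else three_prime_end(iso$strand, iso$starts, iso$ends)
    point_in_peaks(peaks, iso$chrom, pos, window = window)
  }, logical(1))
  mean(supported)
}

#' Recall of the assembly among lowly expressed reference transcripts
#'
#' Denominator: reference transcripts with 0 < TPM <= `cutoff`; numerator:
#' those matched by the assembly.
#'
#' @param assembly List of isoform calls.
#' @param index A [build_reference_index()] result.
#' @param expression data.frame with columns `transcript_id`, `tpm`.
#' @param cutoff TPM cutoff.
#' @return Fraction, or NaN when no reference transcript falls under the
#'   cutoff.
#' @export
recall_under_cutoff <- function(assembly, index, expression, cutoff) {
  stopifnot(all(c("transcript_id", "tpm") %in% names(expression)))
  tpm <- stats::setNames(expression$tpm, expression$transcript_id)
  denom_ids <- vapply(index$transcripts, function(tx) tx$transcript_id,
                      character(1))
  denom_ids <- denom_ids[!is.na(tpm[denom_ids]) & tpm[denom_ids] > 0 &
                           tpm[denom_ids] <= cutoff]
  if (length(denom_ids) == 0L) return(NaN)
  matched <- unique(unlist(lapply(assembly, match_isoform, index = index)))
  sum(denom_ids %in% matched) / length(denom_ids)
}

#' Structural category of an isoform relative to the reference
#'
#' * `FSM` (full-splice match): the intron chain equals a reference chain.
#' * `ISM` (incomplete splice match): the chain is a proper contiguous
#'   sub-chain of some reference chain (consecutive parent junctions).
#' * `NIC` (novel in catalog): every donor and acceptor site is annotated
#'   but the chain is neither a reference chain nor a contiguous sub-chain.
#' * `NNC` (novel not in catalog): at least one splice site is unannotated.
#' * `single_exon`: no junctions.
#'
#' @param isoform An isoform call.
#' @param index A [build_reference_index()] result.
#' @return List with `category` and, for ISM, `parent_id` plus `truncation`
#'   (`"5prime"`, `"3prime"`, `"both"`).
#' @export
classify_structure <- function(isoform, index) {
  ic <- isoform_chain(isoform)
  if (length(ic$starts) == 0L) return(list(category = "single_exon"))
  key <- chain_key(isoform$chrom, isoform$strand, ic$starts, ic$ends)
  if (!is.null(index$chain_lookup[[key]]))
    return(list(category = "FSM",
                parent_id = sort(index$chain_lookup[[key]])[1L]))
  # contiguous sub-chain of some reference transcript?
  for (tx in index$transcripts) {
    if (tx$chrom != isoform$chrom || tx$strand != isoform$strand) next
    pc <- intron_coords(tx$starts, tx$ends)
    pos <- find_contiguous_subchain(ic, pc)
    if (!is.null(pos)) {
      return(list(category = "ISM", parent_id = tx$transcript_id,
                  truncation = ism_truncation_at(pos[1L], pos[2L],
                                                 length(pc$starts),
                                                 isoform$strand)))
    }
  }
  donor_is_start <- isoform$strand == "+"
  all_known <- all(vapply(seq_along(ic$starts), function(j) {
    dk <- if (donor_is_start) ic$starts[j] else ic$ends[j]
    ak <- if (donor_is_start) ic$ends[j] else ic$starts[j]
    is_annotated_site(index, isoform$chrom, isoform$strand, dk, "donor") &&
      is_annotated_site(index, isoform$chrom, isoform$strand, ak, "acceptor")
  }, logical(1)))
  list(category = if (all_known) "NIC" else "NNC")
}

# returns c(i, j) such that chain == parent junctions i..j (genomic order),
# proper sub-chain; NULL otherwise
find_contiguous_subchain <- function(chain, parent) {
  n <- length(chain$starts); m <- length(parent$starts)
  if (n == 0L || n >= m) return(NULL)
  for (i in seq_len(m - n + 1L)) {
    j <- i + n - 1L
    if (all(parent$starts[i:j] == chain$starts) &&
        all(parent$ends[i:j] == chain$ends)) return(c(i, j))
  }
  NULL
}

ism_truncation_at <- function(i, j, m, strand) {
  left_missing <- i > 1L
  right_missing <- j < m
  if (left_missing && right_missing) return("both")
  if (strand == "+") {
    if (right_missing) "3prime" else if (left_missing) "5prime" else "internal"
  } else {
    if (right_missing) "5prime" else if (left_missing) "3prime" else "internal"
  }
}

#' Truncation side of an incomplete splice match
#'
#' Given an ISM chain and its parent chain, reports which transcript end(s)
#' are shortened: `"3prime"` when the sub-chain starts at the parent's first
#' junction (in transcript orientation) but ends early, `"5prime"` when it
#' ends at the last junction but starts late, `"both"` otherwise.
#'
#' @param chain,parent_chain Lists with `starts`/`ends` intron coordinate
#'   vectors (genomic order).
#' @param strand Transcript strand.
#' @return One of `"5prime"`, `"3prime"`, `"both"`, `"internal"`.
#' @export
ism_truncation <- function(chain, parent_chain, strand = "+") {
  pos <- find_contiguous_subchain(chain, parent_chain)
  if (is.null(pos)) stop("chain is not a proper contiguous sub-chain")
  ism_truncation_at(pos[1L], pos[2L], length(parent_chain$starts), strand)
}

#' Relative position of an ISM's start exon within its parent
#'
#' The ordinal (in transcript orientation, 1-based) of the parent exon where
#' the ISM starts, divided by the parent's exon count.
#'
#' @param isoform The ISM isoform call.
#' @param parent The parent [transcript_model()].
#' @return Fraction in (0, 1].
#' @export
relative_start_exon <- function(isoform, parent) {
  ic <- isoform_chain(isoform)
  pc <- intron_coords(parent$starts, parent$ends)
  pos <- find_contiguous_subchain(ic, pc)
  if (is.null(pos)) stop("isoform is not a contiguous sub-chain of parent")
  n_exons <- length(parent$starts)
  ordinal <- if (parent$strand == "+") pos[1L] else n_exons - pos[2L]
  ordinal / n_exons
}

#' Relative intron position within a transcript
#'
#' @param intron_ordinal 1-based intron ordinal in transcript orientation.
#' @param total_introns Total introns of the transcript (> 0).
#' @return `intron_ordinal / total_introns`.
#' @export
relative_intron_position <- function(intron_ordinal, total_introns) {
  if (any(total_introns <= 0L)) stop("total_introns must be positive")
  stopifnot(all(intron_ordinal >= 1L), all(intron_ordinal <= total_introns))
  intron_ordinal / total_introns
}

#' Cumulative distribution of isoform read support
#'
#' @param isoforms List of isoform calls with `n_reads`.
#' @return data.frame with `n_reads` (ascending distinct support counts) and
#'   `cum_fraction` (fraction of isoforms with support <= that count).
#' @export
read_count_cdf <- function(isoforms) {
  if (length(isoforms) == 0L)
    return(data.frame(n_reads = integer(0), cum_fraction = numeric(0)))
  counts <- vapply(isoforms, function(x) x$n_reads, numeric(1))
  xs <- sort(unique(counts))
  data.frame(n_reads = xs,
             cum_fraction = vapply(xs, function(x) mean(counts <= x),
                                   numeric(1)))
}

#' Probability that a transcript yields few reads
#'
#' For a transcript expressed at `tpm` in a run of `total_reads` reads, the
#' number of reads it receives is Binomial(`total_reads`, `tpm` x 1e-6);
#' this returns P(X <= `max_reads`), either by summing the binomial mass
#' (`mode = "exact"`) or by seeded Monte Carlo (`mode = "simulate"`). At
#' 1 TPM in a 1M-read run this exceeds 0.9 — the reason coverage-based
#' filters discard real low-abundance transcripts.
#'
#' @param tpm Expression in transcripts per million.
#' @param total_reads Total reads in the run.
#' @param max_reads Count threshold.
#' @param mode `"exact"` or `"simulate"`.
#' @param n_sims Number of Monte Carlo replicates.
#' @param seed Seed for simulate mode.
#' @return The probability.
#' @export
low_coverage_probability <- function(tpm, total_reads, max_reads = 2L,
                                     mode = c("exact", "simulate"),
                                     n_sims = 1e5, seed = 42L) {
  mode <- match.arg(mode)
  stopifnot(tpm >= 0, total_reads >= 1)
  p <- tpm * 1e-6
  if (p > 1) stop("tpm/1e6 exceeds 1; not a probability")
  if (mode == "exact") return(stats::pbinom(max_reads, total_reads, p))
  set.seed(seed)
  mean(stats::rbinom(n_sims, total_reads, p) <= max_reads)
}
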