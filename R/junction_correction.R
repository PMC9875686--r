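#' Correct one read's splice sites against the annotation
#'
#' For each splice junction of the read, the donor and acceptor sides are
#' handled independently: a side already coinciding with an annotated site of
#' its kind is left untouched; otherwise it is moved to the nearest annotated
#' same-kind site, provided the move is at most `max_shift` bp. The distance
#' is the genomic offset in bp between reported and annotated site. A move
#' that would shrink an exon below 1 bp, close an intron, or reorder blocks
#' is cancelled (that side stays uncorrected) rather than merging exons,
#' which would silently change the intron chain.
#'
#' @param read An [aligned_read()] with at least one junction.
#' @param index A [build_reference_index()] result.
#' @param max_shift Maximum correction distance in bp (default 40).
#' @return `list(read = corrected read, records = data.frame)` where
#'   `records` has one row per applied correction (read_id, junction index,
#'   side, original, corrected, shift).
#' @export
correct_read <- function(read, index, max_shift = 40L) {
  starts <- read$starts; ends <- read$ends
  n <- length(starts)
  if (n < 2L) return(list(read = read, records = empty_correction_records()))
  recs <- list()
  donor_is_start <- read$strand == "+"  # intron start is the donor on "+"
  for (j in seq_len(n - 1L)) {
    # intron j: [ends[j], starts[j+1])
    for (side_is_start in c(TRUE, FALSE)) {
      pos <- if (side_is_start) ends[j] else starts[j + 1L]
      kind <- if (side_is_start == donor_is_start) "donor" else "acceptor"
      if (is_annotated_site(index, read$chrom, read$strand, pos, kind)) next
      hit <- nearest_site(index, read$chrom, read$strand, pos, kind)
      if (is.null(hit) || hit$distance > max_shift) next
      new_pos <- hit$site
      # validity: exon >= 1 bp on the outer side, intron >= 1 bp inside
      ok <- if (side_is_start) {
        new_pos > starts[j] && new_pos < starts[j + 1L]
      } else {
        new_pos > ends[j] && new_pos < ends[j + 1L]
      }
      if (!ok) next
      if (side_is_start) ends[j] <- new_pos else starts[j + 1L] <- new_pos
      recs[[length(recs) + 1L]] <- data.frame(
        read_id = read$read_id, junction = j, side = kind,
        original = pos, corrected = new_pos, shift = new_pos - pos,
        stringsAsFactors = FALSE)
    }
  }
  read$starts <- starts; read$ends <- ends
  records <- if (length(recs)) do.call(rbind, recs) else
    empty_correction_records()
  list(read = read, records = records)
}

empty_correction_records <- function() {
  data.frame(read_id = character(0), junction = integer(0),
             side = character(0), original = integer(0),
             corrected = integer(0), shift = integer(0),
             stringsAsFactors = FALSE)
}

#' Correct all reads
#'
#' Applies [correct_read()] to every spliced read; unspliced (single-block)
#' reads pass through unchanged.
#'
#' @param reads List of [aligned_read()].
#' @param index A [build_reference_index()] result.
#' @param max_shift Maximum correction distance in bp.
#' @return `list(reads, records, summary)`; `summary` counts corrected
#'   junction sides per kind and the sites left uncorrectable (non-annotated
#'   sites with no annotated site within `max_shift`).
#' @export
correct_all <- function(reads, index, max_shift = 40L) {
  records <- vector("list", length(reads))
  out <- vector("list", length(reads))
  uncorrectable <- 0L
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    if (length(r$starts) < 2L) {
      out[[i]] <- r
      records[[i]] <- empty_correction_records()
      next
    }
    cr <- correct_read(r, index, max_shift)
    out[[i]] <- cr$read
    records[[i]] <- cr$records
    ic <- intron_coords(cr$read$starts, cr$read$ends)
    donor_is_start <- r$strand == "+"
    for (j in seq_along(ic$starts)) {
      for (side_is_start in c(TRUE, FALSE)) {
        pos <- if (side_is_start) ic$starts[j] else ic$ends[j]
        kind <- if (side_is_start == donor_is_start) "donor" else "acceptor"
        if (!is_annotated_site(index, r$chrom, r$strand, pos, kind))
          uncorrectable <- uncorrectable + 1L
      }
    }
  }
  records <- do.call(rbind, records) %||% empty_correction_records()
  summary <- list(
    n_reads = length(reads),
    n_spliced = sum(vapply(reads, function(r) length(r$starts) > 1L,
                           logical(1))),
    n_corrected_donor = sum(records$side == "donor"),
    n_corrected_acceptor = sum(records$side == "acceptor"),
    n_uncorrectable_sites = uncorrectable)
  list(reads = out, records = records, summary = summary)
}
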