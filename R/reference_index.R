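#' Build lookup structures over a reference annotation
#'
#' Precomputes everything the correction and filtering stages consult:
#' per-(chrom, strand) sorted sets of annotated donor and acceptor splice
#' sites, annotated TSS and TES positions, the set of annotated junctions,
#' and a dictionary from intron chain to the reference transcript(s) carrying
#' it.
#'
#' Junctions are stored as intron intervals `[start, end)`; the donor is the
#' intron start on the plus strand and the intron end on the minus strand
#' (and vice versa for the acceptor). TSS/TES are strand-aware genomic
#' positions (the TSS of a minus-strand transcript is its rightmost
#' coordinate). Single-exon transcripts contribute TSS/TES but no junctions.
#'
#' @param transcripts List of [transcript_model()] objects.
#' @return A `reference_index` list with elements `donor`, `acceptor`,
#'   `tss`, `tes` (each a named list of sorted integer vectors keyed by
#'   `"chrom|strand"`), `junction_set` (character), `chain_lookup` (named
#'   list chain key -> transcript ids), `transcripts`, `tx_by_id`.
#' @export
build_reference_index <- function(transcripts) {
  donor <- list(); acceptor <- list(); tss <- list(); tes <- list()
  junction_set <- character(0)
  chain_lookup <- list()
  tx_by_id <- list()
  add <- function(lst, key, vals) {
    lst[[key]] <- c(lst[[key]], vals); lst
  }
  for (tx in transcripts) {
    key <- paste0(tx$chrom, "|", tx$strand)
    ic <- intron_coords(tx$starts, tx$ends)
    tss <- add(tss, key, five_prime_end(tx$strand, tx$starts, tx$ends))
    tes <- add(tes, key, three_prime_end(tx$strand, tx$starts, tx$ends))
    if (length(ic$starts) > 0L) {
      if (tx$strand == "+") {
        donor <- add(donor, key, ic$starts)
        acceptor <- add(acceptor, key, ic$ends)
      } else {
        donor <- add(donor, key, ic$ends)
        acceptor <- add(acceptor, key, ic$starts)
      }
      junction_set <- c(junction_set,
                        junction_keys(tx$chrom, tx$strand,
                                      ic$starts, ic$ends))
    }
    ck <- chain_key(tx$chrom, tx$strand, ic$starts, ic$ends)
    chain_lookup[[ck]] <- c(chain_lookup[[ck]], tx$transcript_id)
    tx_by_id[[tx$transcript_id]] <- tx
  }
  sortu <- function(lst) lapply(lst, function(v) sort(unique(v)))
  structure(list(donor = sortu(donor), acceptor = sortu(acceptor),
                 tss = sortu(tss), tes = sortu(tes),
                 junction_set = unique(junction_set),
                 chain_lookup = chain_lookup,
                 transcripts = transcripts, tx_by_id = tx_by_id),
            class = "reference_index")
}

#' Nearest annotated splice site
#'
#' Finds the annotated site of the requested kind on the same chromosome and
#' strand minimizing the absolute distance to `position`. Ties are broken
#' toward the smaller genomic coordinate.
#'
#' @param index A [build_reference_index()] result.
#' @param chrom,strand Location of the query.
#' @param position Query position (0-based).
#' @param site_kind `"donor"` or `"acceptor"`.
#' @return `list(site, distance)` or `NULL` when no site of that kind exists
#'   on the (chrom, strand).
#' @export
nearest_site <- function(index, chrom, strand, position,
                         site_kind = c("donor", "acceptor")) {
  site_kind <- match.arg(site_kind)
  sites <- index[[site_kind]][[paste0(chrom, "|", strand)]]
  if (is.null(sites) || length(sites) == 0L) return(NULL)
  i <- findInterval(position, sites)
  cand <- unique(c(max(i, 1L), min(i + 1L, length(sites))))
  d <- abs(sites[cand] - position)
  best <- cand[which.min(d)]  # which.min takes the first, i.e. smaller site
  list(site = sites[best], distance = abs(sites[best] - position))
}

# membership tests used by correction and filtering
is_annotated_site <- function(index, chrom, strand, position, site_kind) {
  sites <- index[[site_kind]][[paste0(chrom, "|", strand)]]
  !is.null(sites) && position %in% sites
}

is_annotated_junction <- function(index, jkeys) {
  jkeys %in% index$junction_set
}

# nearest annotated TSS distance (Inf when none on that chrom/strand)
nearest_tss_distance <- function(index, chrom, strand, position) {
  sites <- index$tss[[paste0(chrom, "|", strand)]]
  if (is.null(sites) || length(sites) == 0L) return(Inf)
  min(abs(sites - position))
}
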