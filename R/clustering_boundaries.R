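#' Group corrected spliced reads by intron chain
#'
#' Partitions reads exactly by (chrom, strand, intron chain). Per cluster the
#' strand-aware 5' start and 3' end positions of every member are collected
#' (on the minus strand the 5' end is the larger coordinate), together with
#' the number of polyadenylated members.
#'
#' @param reads List of corrected, spliced [aligned_read()] (use
#'   [cluster_single_exon()] for unspliced reads).
#' @return List of `read_cluster` objects with fields `chrom`, `strand`,
#'   `istarts`/`iends` (the chain's intron coordinates), `chain_key`,
#'   `reads`, `start_positions`, `end_positions`, `n_reads`, `n_polya`,
#'   `single_exon = FALSE`.
#' @export
group_by_intron_chain <- function(reads) {
  if (length(reads) == 0L) return(list())
  keys <- vapply(reads, read_chain_key, character(1))
  idx <- split(seq_along(reads), keys)
  lapply(idx, function(ii) {
    members <- reads[ii]
    r1 <- members[[1L]]
    ic <- intron_coords(r1$starts, r1$ends)
    new_cluster(r1$chrom, r1$strand, ic$starts, ic$ends, members,
                single_exon = FALSE)
  })
}

new_cluster <- function(chrom, strand, istarts, iends, members, single_exon) {
  structure(list(
    chrom = chrom, strand = strand,
    istarts = istarts, iends = iends,
    chain_key = chain_key(chrom, strand, istarts, iends),
    reads = members,
    start_positions = vapply(members, function(r)
      five_prime_end(r$strand, r$starts, r$ends), numeric(1)),
    end_positions = vapply(members, function(r)
      three_prime_end(r$strand, r$starts, r$ends), numeric(1)),
    n_reads = length(members),
    n_polya = sum(vapply(members, function(r)
      identical(r$polya, "polyadenylated"), logical(1))),
    single_exon = single_exon), class = "read_cluster")
}

#' Cluster single-exon reads by reciprocal overlap
#'
#' Single-linkage clustering of same-chromosome, same-strand unspliced reads
#' whose reciprocal overlap (shared length divided by the longer of the two
#' span lengths... computed symmetrically as min of the two fractions) is at
#' least `min_overlap_frac`. Resulting clusters have an empty intron chain.
#'
#' @param reads List of single-block [aligned_read()].
#' @param min_overlap_frac Minimum reciprocal overlap fraction (default 0.5).
#' @return List of `read_cluster` objects with `single_exon = TRUE`.
#' @export
cluster_single_exon <- function(reads, min_overlap_frac = 0.5) {
  if (length(reads) == 0L) return(list())
  stopifnot(all(vapply(reads, function(r) length(r$starts) == 1L,
                       logical(1))))
  groups <- split(seq_along(reads), vapply(reads, function(r)
    paste0(r$chrom, "|", r$strand), character(1)))
  out <- list()
  for (ii in groups) {
    n <- length(ii)
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    s <- vapply(reads[ii], function(r) r$starts[1L], integer(1))
    e <- vapply(reads[ii], function(r) r$ends[1L], integer(1))
    if (n > 1L) {
      ir <- IRanges::IRanges(start = s + 1L, end = e)
      hits <- IRanges::findOverlaps(ir, ir)
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      keep <- qh < sh
      for (k in which(keep)) {
        a <- qh[k]; b <- sh[k]
        if (reciprocal_overlap(s[a], e[a], s[b], e[b]) >= min_overlap_frac) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[min(ra, rb)] <- max(ra, rb)
        }
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    for (members in split(ii, roots)) {
      r1 <- reads[[members[1L]]]
      out[[length(out) + 1L]] <- new_cluster(
        r1$chrom, r1$strand, integer(0), integer(0), reads[members],
        single_exon = TRUE)
    }
  }
  out
}

# --- one-dimensional Gaussian mixture fitted by EM --------------------------

em_gmm_1d <- function(x, k, var_floor = 1.0, max_iter = 500L, tol = 1e-8) {
  n <- length(x)
  # deterministic initialization: means at interior quantiles, equal weights
  mu <- as.numeric(stats::quantile(x, probs = (seq_len(k) - 0.5) / k,
                                   type = 1))
  if (anyDuplicated(mu)) mu <- mu + (seq_len(k) - 1L) * 1e-3
  sigma2 <- rep(max(stats::var(x) * 1.0, var_floor), k)
  if (is.na(sigma2[1L])) sigma2 <- rep(var_floor, k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, mu[j], sqrt(sigma2[j])), numeric(n))
    dens <- matrix(dens, nrow = n)
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.xmin
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma2 <- pmax(colSums(resp * (outer(x, mu, "-")^2)) / nk, var_floor)
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(means = mu, variances = sigma2, weights = w, k = k,
       loglik = ll, bic = -2 * ll + (3 * k - 1) * log(n))
}

#' Fit a 1-D Gaussian mixture to boundary positions
#'
#' Fits mixtures with k = 1 .. min(`max_components`, number of distinct
#' positions) by EM in raw genomic coordinates and returns the fit minimizing
#' BIC. A variance floor (default 1 bp^2) prevents singular components on
#' duplicated positions. Initialization is deterministic (quantile-spread
#' means), so a fixed seed yields bit-reproducible fits.
#'
#' @param positions Numeric vector of genomic positions, length >=
#'   `min_gmm_reads`.
#' @param max_components Largest number of components tried (default 3).
#' @param seed Unused by the deterministic initializer; kept so callers can
#'   thread one configuration through.
#' @param var_floor Variance floor in bp^2.
#' @param min_gmm_reads Minimum number of positions (default 3); fewer
#'   signals the median fallback to the caller.
#' @return A `gmm_fit` list: `means`, `variances`, `weights`, `k`, `bic`
#'   (selected fit) and `bic_by_k` for every candidate k.
#' @export
fit_boundary_gmm <- function(positions, max_components = 3L, seed = 42L,
                             var_floor = 1.0, min_gmm_reads = 3L) {
  x <- as.numeric(positions)
  if (length(x) < min_gmm_reads)
    stop("need at least ", min_gmm_reads,
         " positions for a mixture fit; use the median fallback")
  kmax <- max(1L, min(max_components, length(unique(x))))
  fits <- lapply(seq_len(kmax), function(k) em_gmm_1d(x, k, var_floor))
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  best <- fits[[which.min(bics)]]
  best$bic_by_k <- bics
  class(best) <- "gmm_fit"
  best
}

# boundary estimate from a vector of positions: GMM when enough reads,
# median otherwise; primary = rounded mean of the highest-weight component,
# clamped into the observed range.
boundary_from_positions <- function(pos, config) {
  rng <- range(pos)
  if (length(pos) < config$min_gmm_reads || length(unique(pos)) == 1L) {
    primary <- as.integer(round(stats::median(pos)))
    return(list(primary = primary,
                candidates = data.frame(position = primary, weight = 1),
                method = "median"))
  }
  fit <- fit_boundary_gmm(pos, max_components = config$max_components,
                          seed = config$seed,
                          min_gmm_reads = config$min_gmm_reads)
  ord <- order(-fit$weights, fit$means)
  means <- fit$means[ord]; weights <- fit$weights[ord]
  primary <- as.integer(round(means[1L]))
  primary <- min(max(primary, rng[1L]), rng[2L])
  keep <- weights >= config$min_component_weight
  keep[1L] <- TRUE  # the primary component is always reported
  cand_pos <- as.integer(round(means[keep]))
  cand_pos <- pmin(pmax(cand_pos, rng[1L]), rng[2L])
  cand_pos[1L] <- primary
  list(primary = primary,
       candidates = data.frame(position = cand_pos, weight = weights[keep]),
       method = "gmm")
}

#' Estimate TSS and TES for a read cluster
#'
#' The TSS is estimated from the members' 5' start positions and the TES from
#' their 3' end positions, independently, with a Gaussian mixture (clusters
#' below `min_gmm_reads` members fall back to the median). The primary
#' position is the rounded mean of the highest-weight component; minor
#' components with weight >= `min_component_weight` are retained as
#' candidates. The primary TES is additionally constrained to lie beyond the
#' last junction (strand-aware), and the TSS before the first, so the
#' resulting transcript model keeps every exon at >= 1 bp.
#'
#' @param cluster A `read_cluster`.
#' @param config A [filter_config()].
#' @return `list(tss, tes, starts, ends)`: the two boundary estimates plus
#'   the exon blocks of the resulting transcript model (chain exons extended
#'   to primary TSS/TES).
#' @export
estimate_boundaries <- function(cluster, config = filter_config()) {
  stopifnot(cluster$n_reads >= 1L)
  tss <- boundary_from_positions(cluster$start_positions, config)
  tes <- boundary_from_positions(cluster$end_positions, config)
  ni <- length(cluster$istarts)
  if (ni > 0L) {
    if (cluster$strand == "+") {
      tss$primary <- min(tss$primary, cluster$istarts[1L] - 1L)
      tes$primary <- max(tes$primary, cluster$iends[ni] + 1L)
    } else {
      tss$primary <- max(tss$primary, cluster$iends[ni] + 1L)
      tes$primary <- min(tes$primary, cluster$istarts[1L] - 1L)
    }
  } else if (cluster$strand == "+") {
    tes$primary <- max(tes$primary, tss$primary + 1L)
  } else {
    tes$primary <- min(tes$primary, tss$primary - 1L)
  }
  left <- if (cluster$strand == "+") tss$primary else tes$primary
  right <- if (cluster$strand == "+") tes$primary else tss$primary
  starts <- c(left, cluster$iends)
  ends <- c(cluster$istarts, right)
  list(tss = tss, tes = tes, starts = as.integer(starts),
       ends = as.integer(ends))
}
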