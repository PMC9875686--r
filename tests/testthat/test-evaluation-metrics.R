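ref_parent <- function(n_exons, strand = "+", id = "par") {
  starts <- seq(0L, by = 1000L, length.out = n_exons)
  transcript_model(id, "g", "chrE", strand, starts, starts + 200L)
}

# isoform with the contiguous junction sub-chain i..j of a parent
sub_iso <- function(parent, i, j) {
  ic <- list(starts = parent$ends[-length(parent$ends)],
             ends = parent$starts[-1])
  list(chrom = parent$chrom, strand = parent$strand,
       istarts = ic$starts[i:j], iends = ic$ends[i:j],
       starts = c(ic$starts[i] - 150L, ic$ends[i:j]),
       ends = c(ic$starts[i:j], ic$ends[j] + 150L))
}

test_that("matching ignores terminal ends and requires the exact chain", {
  ref <- list(transcript_model("t1", "g", "chrE", "+",
                               c(0L, 1000L, 2000L), c(200L, 1200L, 2200L)))
  idx <- build_reference_index(ref)
  same_chain <- list(chrom = "chrE", strand = "+",
                     istarts = c(200L, 1200L), iends = c(1000L, 2000L),
                     starts = c(80L, 1000L, 2000L),
                     ends = c(200L, 1200L, 2280L))
  expect_equal(match_isoform(same_chain, idx), "t1")
  missing_first <- list(chrom = "chrE", strand = "+",
                        istarts = 1200L, iends = 2000L,
                        starts = c(1000L, 2000L), ends = c(1200L, 2200L))
  expect_null(match_isoform(missing_first, idx))
  expect_null(match_isoform(same_chain, build_reference_index(list())))
})

test_that("precision and recall follow the TP/FP/FN definitions", {
  # 10 reference transcripts, assembly matches 8 of them plus 2 misses
  refs <- lapply(1:10, function(i)
    transcript_model(sprintf("t%02d", i), "g", "chrE", "+",
                     c(i * 10000L, i * 10000L + 1000L),
                     c(i * 10000L + 200L, i * 10000L + 1200L)))
  idx <- build_reference_index(refs)
  hits <- lapply(refs[1:8], function(tx)
    list(transcript_id = paste0("a_", tx$transcript_id), chrom = tx$chrom,
         strand = tx$strand, starts = tx$starts, ends = tx$ends))
  miss <- lapply(1:2, function(i)
    list(transcript_id = sprintf("fp%d", i), chrom = "chrE", strand = "+",
         starts = c(500000L + i * 5000L, 502000L + i * 5000L),
         ends = c(500100L + i * 5000L, 502100L + i * 5000L)))
  pr <- precision_recall(c(hits, miss), idx)
  expect_equal(pr$TP, 8L); expect_equal(pr$FP, 2L); expect_equal(pr$FN, 2L)
  expect_equal(pr$precision, 0.8)
  expect_equal(pr$recall, 0.8)
  # assembly identical to the reference scores perfectly
  all_iso <- lapply(refs, function(tx)
    list(transcript_id = tx$transcript_id, chrom = tx$chrom,
         strand = tx$strand, starts = tx$starts, ends = tx$ends))
  pr2 <- precision_recall(all_iso, idx)
  expect_equal(pr2$precision, 1.0)
  expect_equal(pr2$recall, 1.0)
  # undefined cases are NaN, not zero
  expect_true(is.nan(precision_recall(list(), idx)$precision))
  expect_true(is.nan(precision_recall(all_iso,
                                      build_reference_index(list()))$recall))
})

test_that("matching agrees with brute-force all-pairs comparison", {
  set.seed(130)
  for (rep in 1:50) {
    refs <- lapply(1:6, function(i) {
      r <- random_read(sprintf("t%d", i), strand = "+")
      transcript_model(sprintf("t%d", i), "g", r$chrom, r$strand,
                       r$starts, r$ends)
    })
    idx <- build_reference_index(refs)
    for (k in 1:5) {
      q <- if (runif(1) < 0.6) {
        tx <- refs[[sample(6, 1)]]
        list(chrom = tx$chrom, strand = tx$strand,
             starts = tx$starts, ends = tx$ends)
      } else {
        r <- random_read("q", strand = "+")
        list(chrom = r$chrom, strand = r$strand,
             starts = r$starts, ends = r$ends)
      }
      expect_equal(match_isoform(q, idx), oracle_match(q, refs))
    }
  }
})

test_that("terminal support honors the +/- 25 bp peak window", {
  iso_at <- function(tss) list(chrom = "chrE", strand = "+",
                               starts = c(tss, tss + 2000L),
                               ends = c(tss + 500L, tss + 2500L))
  peaks <- peak_set(data.frame(chrom = "chrE", start = 990L, end = 1010L,
                               strand = "."), "cage")
  expect_equal(boundary_support_rate(list(iso_at(1000L)), peaks, "tss"), 1.0)
  # nearest peak edge 30 bp away: unsupported at window 25
  peaks2 <- peak_set(data.frame(chrom = "chrE", start = 1030L, end = 1040L,
                                strand = "."), "cage")
  expect_equal(boundary_support_rate(list(iso_at(1000L)), peaks2, "tss"), 0.0)
  expect_equal(boundary_support_rate(list(iso_at(1000L)), peaks2, "tss",
                                     window = 40L), 1.0)
  expect_true(is.nan(boundary_support_rate(list(), peaks, "tss")))
  # monotone non-decreasing in the window
  rates <- vapply(c(0L, 10L, 25L, 50L, 200L), function(w)
    boundary_support_rate(list(iso_at(1000L), iso_at(3000L)), peaks2,
                          "tss", window = w), numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("low-expression recall counts matched references under the cutoff", {
  refs <- lapply(1:10, function(i)
    transcript_model(sprintf("t%02d", i), "g", "chrE", "+",
                     c(i * 10000L, i * 10000L + 1000L),
                     c(i * 10000L + 200L, i * 10000L + 1200L)))
  idx <- build_reference_index(refs)
  expr <- data.frame(transcript_id = sprintf("t%02d", 1:10),
                     tpm = c(rep(0.5, 10)))
  asm <- lapply(refs[1:7], function(tx)
    list(chrom = tx$chrom, strand = tx$strand,
         starts = tx$starts, ends = tx$ends))
  expect_equal(recall_under_cutoff(asm, idx, expr, cutoff = 1), 0.7)
  expect_true(is.nan(recall_under_cutoff(asm, idx, expr, cutoff = 0.1)))
})

test_that("structural categories follow the FSM/ISM/NIC/NNC definitions", {
  par6 <- ref_parent(7)  # 7 exons, 6 junctions
  idx <- build_reference_index(list(par6))
  # contiguous sub-chain (junctions 2..4) is ISM
  ism <- sub_iso(par6, 2, 4)
  cls <- classify_structure(ism, idx)
  expect_equal(cls$category, "ISM")
  expect_equal(cls$parent_id, "par")
  # the full chain is FSM and coincides with a successful match
  fsm <- sub_iso(par6, 1, 6)
  fsm$starts[1] <- 0L; fsm$ends[length(fsm$ends)] <- 6200L
  expect_equal(classify_structure(fsm, idx)$category, "FSM")
  expect_false(is.null(match_isoform(fsm, idx)))
  # known sites in an unseen combination (skipping junctions) is NIC
  nic <- list(chrom = "chrE", strand = "+",
              istarts = par6$ends[c(1, 4)], iends = par6$starts[c(2, 5)],
              starts = c(0L, par6$starts[2], par6$starts[5]),
              ends = c(par6$ends[1], par6$ends[4], par6$ends[7]))
  expect_equal(classify_structure(nic, idx)$category, "NIC")
  # one unannotated acceptor makes it NNC
  nnc <- sub_iso(par6, 2, 4)
  nnc$iends[1] <- nnc$iends[1] + 7L
  nnc$starts[2] <- nnc$starts[2] + 7L
  expect_equal(classify_structure(nnc, idx)$category, "NNC")
  # single-exon stands apart
  se <- list(chrom = "chrE", strand = "+", istarts = integer(0),
             iends = integer(0), starts = 0L, ends = 500L)
  expect_equal(classify_structure(se, idx)$category, "single_exon")
})

test_that("each spliced isoform falls in exactly one category", {
  set.seed(140)
  par6 <- ref_parent(7)
  idx <- build_reference_index(list(par6))
  cats <- c("FSM", "ISM", "NIC", "NNC", "single_exon")
  for (i in 1:50) {
    r <- random_read("q", strand = "+")
    q <- list(chrom = par6$chrom, strand = "+",
              starts = r$starts, ends = r$ends)
    got <- classify_structure(q, idx)$category
    expect_true(got %in% cats)
    matched <- !is.null(match_isoform(q, idx))
    if (length(r$starts) > 1)
      expect_equal(got == "FSM", matched)
  }
})

test_that("ISM truncation typing is strand-aware", {
  par5 <- ref_parent(6)          # 5 junctions
  pc <- list(starts = par5$ends[-6], ends = par5$starts[-1])
  take <- function(i, j) list(starts = pc$starts[i:j], ends = pc$ends[i:j])
  expect_equal(ism_truncation(take(1, 3), pc, "+"), "3prime")
  expect_equal(ism_truncation(take(3, 5), pc, "+"), "5prime")
  expect_equal(ism_truncation(take(2, 4), pc, "+"), "both")
  expect_equal(ism_truncation(take(1, 3), pc, "-"), "5prime")
  expect_equal(ism_truncation(take(3, 5), pc, "-"), "3prime")
  expect_error(ism_truncation(list(starts = 1L, ends = 5L), pc, "+"),
               "sub-chain")
})

test_that("relative start-exon position divides ordinal by exon count", {
  par10 <- ref_parent(10)
  expect_equal(relative_start_exon(sub_iso(par10, 3, 9), par10), 0.3)
  expect_equal(relative_start_exon(sub_iso(par10, 1, 5), par10), 0.1)
  # minus strand: ordinals count 5' to 3' in transcript orientation.
  # junctions 3..5 of a 6-exon minus-strand parent span genomic exons 3..6;
  # the 5'-most of those is genomic exon 6 = transcript exon 1
  par6m <- ref_parent(6, strand = "-")
  expect_equal(relative_start_exon(sub_iso(par6m, 3, 5), par6m), 1 / 6)
  expect_equal(relative_start_exon(sub_iso(par6m, 1, 2), par6m), 4 / 6)
})

test_that("relative intron position is ordinal over total", {
  expect_equal(relative_intron_position(7, 14), 0.5)
  expect_equal(relative_intron_position(1, 1), 1.0)
  expect_error(relative_intron_position(1, 0), "positive")
})

test_that("read-count CDF is a proper cumulative fraction", {
  iso <- lapply(c(1, 1, 2, 5), function(n) list(n_reads = n))
  cdf <- read_count_cdf(iso)
  expect_equal(cdf$cum_fraction[cdf$n_reads == 2], 0.75)
  expect_equal(cdf$cum_fraction[nrow(cdf)], 1.0)
  expect_true(all(diff(cdf$cum_fraction) >= 0))
  expect_equal(nrow(read_count_cdf(list())), 0)
})

test_that("low-coverage probability matches the binomial and its Poisson limit", {
  p <- low_coverage_probability(1, 1e6, 2)
  expect_gt(p, 0.90)
  expect_lt(abs(p - 2.5 * exp(-1)), 0.002)
  expect_equal(low_coverage_probability(0, 1e6, 2), 1.0)
  expect_error(low_coverage_probability(2e6, 10, 2), "exceeds")
  sim <- low_coverage_probability(1, 1e6, 2, mode = "simulate",
                                  n_sims = 1e5, seed = 5)
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(sim - p), 3 * se)
})
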