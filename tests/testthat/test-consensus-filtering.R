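test_that("junction support counts one per containing read", {
  r1 <- aligned_read("a", "chr1", "+", c(0L, 200L), c(100L, 300L))
  r2 <- aligned_read("b", "chr1", "+", c(10L, 200L), c(100L, 280L))
  r3 <- aligned_read("c", "chr1", "+", c(0L, 200L), c(100L, 300L))
  sup <- count_junction_support(list(r1, r2, r3))
  expect_equal(unname(sup[["chr1|+|100-200"]]), 3L)
  # a read with 4 junctions contributes once to each
  r4 <- aligned_read("d", "chr1", "+",
                     c(0L, 200L, 400L, 600L, 800L),
                     c(100L, 300L, 500L, 700L, 900L))
  sup4 <- count_junction_support(list(r4))
  expect_length(sup4, 4)
  expect_true(all(sup4 == 1L))
})

test_that("junction support equals brute-force enumeration on random reads", {
  set.seed(110)
  reads <- lapply(1:100, function(i) random_read(sprintf("r%d", i)))
  got <- count_junction_support(reads)
  exp <- oracle_junction_support(reads)
  expect_equal(got[sort(names(got))], exp[sort(names(exp))])
})

make_clusters <- function(reads) {
  cl <- group_by_intron_chain(reads)
  for (i in seq_along(cl)) cl[[i]]$boundaries <- estimate_boundaries(cl[[i]])
  cl
}

test_that("novel junctions below the read-support threshold drop clusters", {
  idx <- build_reference_index(fixture_reference())
  # novel junction 100-900 on chrFix
  novel1 <- aligned_read("n1", "chrFix", "+", c(0L, 900L), c(100L, 1000L))
  novel2 <- aligned_read("n2", "chrFix", "+", c(5L, 900L), c(100L, 1000L))
  annot <- read_from_tx(idx$transcripts[[1]], "k1")
  sup1 <- count_junction_support(list(novel1, annot))
  f <- filter_novel_junctions(make_clusters(list(novel1, annot)), idx, sup1)
  expect_length(f$kept, 1)
  expect_length(f$dropped, 1)
  # with two supporting reads the novel junction survives
  sup2 <- count_junction_support(list(novel1, novel2, annot))
  f2 <- filter_novel_junctions(make_clusters(list(novel1, novel2, annot)),
                               idx, sup2)
  expect_length(f2$kept, 2)
  # an annotated chain with a single read is exempt
  f3 <- filter_novel_junctions(make_clusters(list(annot)), idx,
                               count_junction_support(list(annot)))
  expect_length(f3$dropped, 0)
})

test_that("novel chains need polyadenylation evidence; annotated are exempt", {
  idx <- build_reference_index(fixture_reference())
  mk_novel <- function(polya, n = 5)
    lapply(seq_len(n), function(i)
      aligned_read(sprintf("nv%d", i), "chrFix", "+",
                   c(0L, 900L), c(100L, 1000L), polya = polya))
  f <- filter_polya(make_clusters(mk_novel("not_polyadenylated")), idx)
  expect_length(f$kept, 0)
  f2 <- filter_polya(make_clusters(mk_novel("polyadenylated", 1)), idx)
  expect_length(f2$kept, 1)
  ref_reads <- list(read_from_tx(idx$transcripts[[1]], "k1",
                                 polya = "not_polyadenylated"))
  f3 <- filter_polya(make_clusters(ref_reads), idx)
  expect_length(f3$kept, 1)  # reference chain exempt
})

test_that("TSS filter accepts annotation or CAGE evidence within the window", {
  ref <- fixture_reference()  # REFA TSS at 1000 (+)
  idx <- build_reference_index(ref)
  near <- aligned_read("near", "chrFix", "+",
                       c(1030L, 2000L), c(1200L, 2200L))
  far <- aligned_read("far", "chrFix", "+",
                      c(1300L, 2000L), c(1450L, 2200L))
  cl <- make_clusters(list(near, far))
  f <- filter_tss(cl, idx, cage = NULL, tss_window = 50L)
  expect_length(f$kept, 1)
  expect_equal(f$kept[[1]]$tss_evidence, "annotated")
  cage <- peak_set(data.frame(chrom = "chrFix", start = 1290L, end = 1310L,
                              strand = "+"), "cage")
  f2 <- filter_tss(cl, idx, cage = cage, tss_window = 50L)
  expect_length(f2$kept, 2)
  expect_setequal(vapply(f2$kept, function(x) x$tss_evidence, character(1)),
                  c("annotated", "cage"))
})

test_that("filters are monotone and order-independent on the kept set", {
  set.seed(120)
  cfg <- sim_config(n_genes = 8L, n_reads = 800L, seed = 9L)
  truth <- generate_annotation(cfg)
  idx <- build_reference_index(truth)
  sim <- simulate_reads(truth, assign_expression(truth, cfg), cfg)
  corr <- correct_all(sim$reads, idx)
  spliced <- Filter(function(r) length(r$starts) > 1, corr$reads)
  sup <- count_junction_support(spliced)
  cl <- group_by_intron_chain(spliced)
  for (i in seq_along(cl)) cl[[i]]$boundaries <- estimate_boundaries(cl[[i]])
  orders <- list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))
  apply_filter <- function(clusters, which)
    switch(which,
           filter_novel_junctions(clusters, idx, sup)$kept,
           filter_polya(clusters, idx)$kept,
           filter_tss(clusters, idx)$kept)
  finals <- lapply(orders, function(ord) {
    cur <- cl
    sizes <- integer(0)
    for (w in ord) {
      nxt <- apply_filter(cur, w)
      expect_lte(length(nxt), length(cur))
      cur <- nxt
    }
    sort(vapply(cur, function(x) x$chain_key, character(1)))
  })
  expect_equal(finals[[2]], finals[[1]])
  expect_equal(finals[[3]], finals[[1]])
})

test_that("a noise-free run recovers exactly the sampled truth chains", {
  cfg <- noise_free_config(n_genes = 8L, n_reads = 1500L, seed = 21L)
  truth <- generate_annotation(cfg)
  expr <- assign_expression(truth, cfg)
  sim <- simulate_reads(truth, expr, cfg, out_dir = tempfile("sim"))
  res <- call_isoforms(sim$sam_path, sim$gtf_path, polya = sim$polya_path)
  idx <- build_reference_index(truth)
  pr <- precision_recall(res$isoforms, idx)
  expect_equal(pr$precision, 1.0)
  sampled <- unique(sim$truth$transcript_id)
  expect_setequal(pr$matched_ref_ids, sampled)
})

test_that("truncated 5'-shortened chains without TSS support are removed", {
  ref <- fixture_reference()
  refA <- ref[[1]]  # + strand, exons 1000-1200, 2000-2200, 3000-3200
  idx <- build_reference_index(ref)
  full <- lapply(1:3, function(i) read_from_tx(refA, sprintf("f%d", i)))
  # truncated reads: start inside exon 2, keeping only the last junction
  trunc <- lapply(1:4, function(i)
    aligned_read(sprintf("t%d", i), "chrFix", "+",
                 c(2100L, 3000L), c(2200L, 3200L),
                 polya = "polyadenylated"))
  res <- call_isoforms(c(full, trunc), ref)
  chains <- vapply(res$isoforms, function(x) x$chain_key, character(1))
  expect_length(res$isoforms, 1)
  expect_equal(res$isoforms[[1]]$n_reads, 3L)
  expect_false("chrFix|+|2200-3000" %in% chains)
  expect_length(res$dropped$tss, 1)
})

test_that("one TSS-supported polyadenylated read rescues a low-abundance isoform", {
  ref <- fixture_reference()
  reads <- c(lapply(1:4, function(i) read_from_tx(ref[[2]], sprintf("b%d", i))),
             list(read_from_tx(ref[[1]], "solo")))
  res <- call_isoforms(reads, ref)
  ids <- vapply(res$isoforms, function(x) x$gene_id, character(1))
  n_reads <- vapply(res$isoforms, function(x) x$n_reads, integer(1))
  expect_setequal(ids, c("REFA", "REFB"))
  expect_true(1L %in% n_reads)
  # a coverage-driven baseline (>= 3 reads) drops the singleton
  baseline <- Filter(function(x) x$n_reads >= 3L, res$isoforms)
  expect_setequal(vapply(baseline, function(x) x$gene_id, character(1)),
                  "REFB")
})

test_that("merging assemblies is nonredundant and idempotent", {
  cfg <- noise_free_config(n_genes = 6L, n_reads = 600L, seed = 31L)
  truth <- generate_annotation(cfg)
  expr <- assign_expression(truth, cfg)
  sim <- simulate_reads(truth, expr, cfg)
  res <- call_isoforms(sim$reads, truth)
  a <- res$isoforms
  m_aa <- merge_assemblies(list(a, a))
  expect_length(m_aa, length(a))
  reads_a <- sum(vapply(a, function(x) x$n_reads, numeric(1)))
  expect_equal(sum(vapply(m_aa, function(x) x$n_reads, numeric(1))),
               2 * reads_a)
  # disjoint assemblies concatenate
  half <- length(a) %/% 2
  m_disj <- merge_assemblies(list(a[seq_len(half)],
                                  a[seq(half + 1, length(a))]))
  expect_length(m_disj, length(a))
})

test_that("emitted isoforms carry evidence and write a valid GTF", {
  cfg <- noise_free_config(n_genes = 5L, n_reads = 400L, seed = 41L)
  truth <- generate_annotation(cfg)
  sim <- simulate_reads(truth, assign_expression(truth, cfg), cfg)
  out <- tempfile(fileext = ".gtf")
  res <- call_isoforms(sim$reads, truth, out_gtf = out)
  expect_true(all(vapply(res$isoforms, function(x)
    x$tss_evidence != "none", logical(1))))
  back <- parse_annotation(out)
  expect_length(back, length(res$isoforms))
})
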