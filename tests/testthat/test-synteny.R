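# shared fixture: a genome with genes flanking one large cluster
synteny_fixture <- function(seed = 51L) {
  cfg <- sim_config(genome_length = 60000L, rng_seed = seed,
                    te_families = list(),
                    genes = list(gene_model(5L, 200L, 400L),
                                 gene_model(5L, 200L, 400L),
                                 gene_model(4L, 250L, 500L),
                                 gene_model(4L, 250L, 500L)),
                    clusters = list(cluster_spec(4000L, 30L, depth = 300L)))
  simulate_genome(cfg)
}

test_that("flanking exons are the nearest n per side, in genomic order", {
  set.seed(1)
  exs <- tibble::tibble(
    chrom = "chr1",
    start = as.integer(seq(1000L, 49000L, by = 2000L)),
    strand = "+", gene_id = "g1", feature = "exon")
  exs$end <- exs$start + 150L
  genes <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", start = 1000L, end = 49150L, strand = "+",
                   gene_id = "g1", feature = "gene"), exs)
  genome <- c(chr1 = rand_seq(60000))
  cl <- tibble::tibble(chrom = "chr1", start = 50000L, end = 52000L,
                       cluster_id = "cl1")
  # 25 exons upstream, none downstream: exactly the nearest 10 are chosen
  anc <- flanking_exons(cl, genes, genome)
  expect_equal(nrow(anc), 10L)
  expect_true(all(anc$side == "up"))
  expect_equal(max(anc$end), 49150L)
  expect_equal(min(anc$start), 31000L)
  expect_equal(anc$seq[1], substr(genome[["chr1"]], anc$start[1] + 1, anc$end[1]))
  # only 4 exons on the chromosome: the anchor holds 4
  anc4 <- flanking_exons(cl, genes[c(1, 2:5), ], genome)
  expect_equal(nrow(anc4), 4L)
  # clusters not longer than 1 kb are excluded
  small <- tibble::tibble(chrom = "chr1", start = 50000L, end = 50999L,
                          cluster_id = "tiny")
  expect_error(flanking_exons(small, genes, genome), "1000")
  # chromosome without exons: empty anchor with a warning
  nogenes <- genes[0, ]
  expect_warning(anc0 <- flanking_exons(cl, nogenes, genome), "no exons")
  expect_equal(nrow(anc0), 0L)
})

test_that("local similarity search finds exact, partial and minus-strand hits", {
  set.seed(61)
  target <- c(t1 = rand_seq(20000))
  q <- substr(target[["t1"]], 5001, 5600)
  hit <- local_similarity_search(q, target)
  expect_gte(nrow(hit), 1L)
  expect_equal(hit$t_start[1], 5000L)
  expect_equal(hit$t_end[1], 5600L)
  expect_equal(hit$identity[1], 1)
  expect_equal(hit$strand[1], "+")
  expect_equal(hit$score[1], 600)
  # reverse-complement query: same locus, minus strand, same score
  hit_rc <- local_similarity_search(revcomp(q), target)
  expect_equal(hit_rc$strand[1], "-")
  expect_equal(hit_rc$score[1], hit$score[1])
  expect_equal(hit_rc$t_start[1], hit$t_start[1])
  # 1,000-bp query whose only similarity covers 80 bp of it is discarded
  q2 <- paste0(rand_seq(500), substr(target[["t1"]], 9001, 9080), rand_seq(420))
  hit2 <- local_similarity_search(q2, target)
  expect_false(any(hit2$t_start >= 8900 & hit2$t_start <= 9100))
  expect_error(local_similarity_search("", target), "non-empty")
})

test_that("hit grouping respects the span bound and detects collinearity", {
  mk <- function(ord, chrom, t) tibble::tibble(
    exon_order = ord, chrom = chrom, t_start = t, t_end = t + 100L, score = 50)
  # ten collinear exons in one window
  g1 <- group_hits(mk(1:10, "t1", seq(1000L, 10000L, by = 1000L)))
  expect_equal(nrow(g1), 1L)
  expect_equal(g1$n_exons, 10L)
  expect_true(g1$collinear)
  # split across two chromosomes: two groups
  g2 <- group_hits(dplyr::bind_rows(mk(1:5, "t1", seq(1000L, 5000L, 1000L)),
                                    mk(6:10, "t2", seq(1000L, 5000L, 1000L))))
  expect_equal(nrow(g2), 2L)
  # shuffled target order within the window: grouped but flagged non-collinear
  g3 <- group_hits(mk(c(3L, 1L, 4L, 2L), "t1", seq(1000L, 4000L, 1000L)))
  expect_equal(g3$n_exons, 4L)
  expect_false(g3$collinear)
  # hits farther apart than the span bound split
  g4 <- group_hits(mk(1:2, "t1", c(1000L, 3e6)), max_span = 1e6)
  expect_equal(nrow(g4), 2L)
})

test_that("self-comparison calls every eligible cluster syntenic", {
  sim <- synteny_fixture()
  calls <- synteny_screen(sim$truth$clusters, sim$genes, sim$genome, sim$genome,
                          clusters_b = sim$truth$clusters)
  eligible <- calls[calls$eligible, ]
  expect_gte(nrow(eligible), 1L)
  expect_true(all(eligible$syntenic))
  expect_true(all(eligible$cluster_body_conserved))
  expect_true(all(eligible$cluster_nearby))
  # on self-comparison every anchor exon finds its own locus
  for (i in seq_len(nrow(eligible))) {
    cl <- sim$truth$clusters[sim$truth$clusters$cluster_id == eligible$cluster_id[i], ]
    anc <- flanking_exons(cl, sim$genes, sim$genome)
    expect_equal(eligible$n_homologous_exons[i], nrow(anc))
  }
})

test_that("exactly three homologous exons is below the synteny threshold", {
  sim <- synteny_fixture()
  cl <- sim$truth$clusters[1, ]
  anchor <- flanking_exons(cl, sim$genes, sim$genome)
  # a target containing copies of only three anchor exons
  three <- paste(c(rand_seq(2000), anchor$seq[1], rand_seq(1000), anchor$seq[2],
                   rand_seq(1000), anchor$seq[3], rand_seq(2000)), collapse = "")
  call3 <- call_synteny(anchor, c(tx = three))
  expect_equal(call3$n_homologous_exons, 3L)
  expect_false(call3$syntenic)
  # four homologous exons clears it
  four <- paste(c(three, anchor$seq[4], rand_seq(500)), collapse = "")
  call4 <- call_synteny(anchor, c(tx = four))
  expect_equal(call4$n_homologous_exons, 4L)
  expect_true(call4$syntenic)
  # an empty anchor is non-syntenic with a diagnostic
  expect_warning(c0 <- call_synteny(anchor[0, ], c(tx = three)), "empty anchor")
  expect_false(c0$syntenic)
})

test_that("cluster turnover at conserved loci: flanks kept, body lost", {
  sim <- synteny_fixture()
  cid <- sim$truth$clusters$cluster_id[1]
  # second genome: mildly diverged everywhere, cluster body replaced
  gen_b <- derive_genome(sim, d = 0.03, drop_cluster_bodies = cid, seed = 77L)
  calls <- synteny_screen(sim$truth$clusters, sim$genes, sim$genome, gen_b$genome)
  call <- calls[calls$cluster_id == cid & calls$eligible, ]
  expect_true(call$syntenic)
  expect_false(call$cluster_body_conserved)
  # without the deletion the body survives
  gen_c <- derive_genome(sim, d = 0.03, seed = 77L)
  calls_c <- synteny_screen(sim$truth$clusters, sim$genes, sim$genome, gen_c$genome)
  expect_true(all(calls_c$cluster_body_conserved[calls_c$eligible]))
})
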