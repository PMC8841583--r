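test_that("family diversity is mean pairwise K2P distance", {
  expect_warning(d1 <- family_diversity("ACGTACGT"), "single-copy")
  expect_equal(d1, 0)
  expect_equal(family_diversity(c("ACGTACGTAC", "ACGTACGTAC")), 0)
  # two copies differing by 1 transition in 10 sites: pairwise K2P of P=0.1
  a <- "ACGTACGTAC"
  b <- "GCGTACGTAC"   # A->G transition at position 1
  expect_equal(family_diversity(c(a, b)), kimura2p(0.1, 0))
  # independent K2P branches add: copies at d from consensus sit ~2d apart
  set.seed(5)
  cons <- rand_seq(8000)
  copies <- replicate(6, mutate_copy(cons, 0.05, 2))
  expect_lt(abs(family_diversity(copies) - 0.10), 0.012)
})

test_that("overlap resolution gives contested bases to the lower-diversity family", {
  ann <- tibble::tibble(
    chrom = "chr1",
    start = c(100L, 250L), end = c(300L, 400L),
    family = c("old", "young"), class = c("DNA", "LINE"),
    superfamily = c("x", "y"), divergence = c(0.10, 0.02))
  div <- c(old = 0.10, young = 0.02)
  res <- resolve_repeat_overlaps(ann, div)
  # the 50 contested bases [250,300) go to the young family
  y <- res[res$family == "young", ]
  expect_equal(c(y$start, y$end), c(250L, 400L))
  o <- res[res$family == "old", ]
  expect_equal(c(o$start, o$end), c(100L, 250L))
  # disjoint annotations are untouched
  ann2 <- dplyr::mutate(ann, start = c(100L, 500L), end = c(300L, 700L))
  expect_equal(nrow(resolve_repeat_overlaps(ann2, div)), 2L)
  expect_error(resolve_repeat_overlaps(ann, c(old = 0.1)), "young")
})

test_that("overlap resolution equals the per-base brute-force oracle", {
  set.seed(9)
  G <- 5000L
  n <- 12L
  ann <- tibble::tibble(
    chrom = "chr1",
    start = as.integer(sample.int(G - 400L, n)),
    family = sprintf("fam%02d", seq_len(n)),
    class = sample(c("DNA", "LINE", "LTR"), n, TRUE),
    superfamily = "s")
  ann$end <- ann$start + as.integer(sample(100:400, n, TRUE))
  div <- setNames(runif(n, 0.01, 0.3), ann$family)
  res <- resolve_repeat_overlaps(ann, div)
  # intervals are disjoint
  res <- dplyr::arrange(res, start)
  expect_true(all(res$start[-1] >= res$end[-nrow(res)]))
  # per-base ownership matches the oracle
  owner <- oracle_perbase_resolve(ann, div, G)
  got <- rep(NA_character_, G)
  for (i in seq_len(nrow(res))) got[(res$start[i] + 1L):res$end[i]] <- res$family[i]
  expect_identical(got, ifelse(is.na(owner), NA_character_, ann$family[owner]))
})

test_that("genome classification honours the transposon > exon > intron priority", {
  # toy 1,000-bp genome: 240 bp DNA transposon, 88 bp retrotransposon,
  # one gene [500,856) with a 56-bp exon -> intron 300 bp
  repeats <- tibble::tibble(
    chrom = "chr1", start = c(0L, 300L), end = c(240L, 388L),
    family = c("dna1", "rt1"), class = c("DNA", "LINE"),
    superfamily = c("hAT", "L1"), divergence = c(0.05, 0.1))
  genes <- tibble::tibble(
    chrom = "chr1", start = c(500L, 520L), end = c(856L, 576L),
    strand = "+", gene_id = "gene01", feature = c("gene", "exon"))
  cmap <- classify_genome(repeats, genes, c(chr1 = 1000L))
  ft <- fraction_table(cmap)
  frac <- setNames(ft$fraction, ft$category)
  expect_equal(unname(frac["dna_transposon"]), 0.24)
  expect_equal(unname(frac["retrotransposon"]), 0.088)
  expect_equal(unname(frac["exon"]), 0.056)
  expect_equal(unname(frac["intron"]), 0.30)
  expect_equal(unname(frac["other"]), 0.316)
  expect_equal(sum(ft$fraction), 1)
  # per-base partition: every base has exactly one label
  lab <- perbase_categories(cmap, "chr1", 1000L)
  expect_false(any(is.na(lab)))
})

test_that("an exon overlapping a transposon is labelled transposon", {
  repeats <- tibble::tibble(chrom = "chr1", start = 100L, end = 300L,
                            family = "dna1", class = "DNA",
                            superfamily = "hAT", divergence = 0.05)
  genes <- tibble::tibble(
    chrom = "chr1", start = c(150L, 150L), end = c(500L, 350L),
    strand = "+", gene_id = "g1", feature = c("gene", "exon"))
  cmap <- classify_genome(repeats, genes, c(chr1 = 1000L))
  lab <- perbase_categories(cmap, "chr1", 1000L)
  expect_true(all(lab[151:300] == "dna_transposon"))
  expect_true(all(lab[301:350] == "exon"))
  expect_true(all(lab[351:500] == "intron"))
  # an exon escaping its gene is a validation error
  bad <- dplyr::mutate(genes, end = c(500L, 600L))
  expect_error(classify_genome(repeats, bad, c(chr1 = 1000L)), "outside")
  # empty annotations: everything is "other"
  ft0 <- fraction_table(classify_genome(repeats[0, ], genes[0, ], c(chr1 = 1000L)))
  expect_equal(ft0$fraction[ft0$category == "other"], 1)
})

test_that("piRNA fractions attribute weight by the 5' base's category", {
  repeats <- tibble::tibble(chrom = "chr1", start = 100L, end = 400L,
                            family = "rt1", class = "LTR",
                            superfamily = "Gypsy", divergence = 0.08)
  cmap <- classify_genome(repeats,
                          tibble::tibble(chrom = character(), start = integer(),
                                         end = integer(), strand = character(),
                                         gene_id = character(), feature = character()),
                          c(chr1 = 1000L))
  inside <- aln_tbl(fp = c(150L, 399L, 250L), strand = c("+", "-", "+"), weight = 2)
  ft <- fraction_table(cmap, alignments = inside)
  expect_equal(ft$fraction[ft$category == "retrotransposon"], 1)
  # a read whose 5' base is outside counts elsewhere; fractions still sum to 1
  mixed <- dplyr::bind_rows(inside, aln_tbl(fp = 800L, strand = "+", weight = 6))
  ft2 <- fraction_table(cmap, alignments = mixed)
  expect_equal(ft2$fraction[ft2$category == "retrotransposon"], 0.5)
  expect_equal(sum(ft2$fraction), 1)
})
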