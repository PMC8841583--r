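test_that("density detector applies the 1 locus/kb and 10-locus filters", {
  # 12 loci over 800 bp: density 15/kb, kept
  fp12 <- as.integer(seq(1000, 1799, length.out = 12))
  cl <- detect_density(aln_tbl(fp12, "+"))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_loci, 12L)
  expect_equal(cl$density, 12 / ((cl$end - cl$start) / 1000))
  expect_gte(cl$density, 1)
  # 9 loci in 800 bp: fails the 10-locus rule
  fp9 <- as.integer(seq(1000, 1799, length.out = 9))
  expect_equal(nrow(detect_density(aln_tbl(fp9, "+"))), 0L)
  # 10 loci spread over 20 kb (0.5/kb): fails the density rule
  fp10 <- as.integer(seq(1000, 20999, length.out = 10))
  expect_equal(nrow(detect_density(aln_tbl(fp10, "+"))), 0L)
})

test_that("raising min_loci never increases the cluster count", {
  set.seed(19)
  aln <- aln_tbl(sort(sample.int(50000L, 300)), "+")
  n <- vapply(c(2L, 5L, 10L, 20L, 50L), function(k)
    nrow(detect_density(aln, min_loci = k)), integer(1))
  expect_true(all(diff(n) <= 0))
})

test_that("assembly detector chains, filters and merges fragments", {
  # two ~300-bp fragments 200 bp apart, total weight 80 -> one kept cluster
  frag1 <- as.integer(seq(1000, 1270, by = 27))   # reads of 30 nt, gaps < 50
  frag2 <- as.integer(seq(1500, 1770, by = 27))
  aln <- aln_tbl(c(frag1, frag2), "+", length = 30L, weight = 4)
  cl <- detect_assembly(aln)
  expect_equal(nrow(cl), 1L)
  expect_gte(cl$end - cl$start, 500L)
  expect_equal(cl$read_weight, 4 * length(c(frag1, frag2)))
  # a single 400-bp fragment fails min_len = 500
  lone <- aln_tbl(as.integer(seq(1000, 1370, by = 27)), "+", length = 30L, weight = 4)
  expect_equal(nrow(detect_assembly(lone)), 0L)
  # a heavy but sub-min_weight cluster is dropped
  light <- aln_tbl(c(frag1, frag2), "+", length = 30L, weight = 1)
  expect_equal(nrow(detect_assembly(light)), 0L)
})

test_that("cluster union merges overlapping detections into one interval", {
  aln <- aln_tbl(as.integer(seq(1000, 2990, by = 40)), "+")
  d <- detect_density(aln, sample = "ovary")
  a <- detect_assembly(aln, sample = "ovary")
  mk <- function(s, e, method) {
    x <- aln_tbl(c(s, e - 26L), "+")
    cl <- tibble::tibble(chrom = "chr1", start = s, end = e, n_loci = 2L,
                         read_weight = 2, density = 1, strand_ratio = 1,
                         sample = "ovary", method = method)
    cl
  }
  one <- mk(1000L, 2000L, "density"); two <- mk(1500L, 3000L, "assembly")
  u <- union_clusters(one, two, aln)
  expect_equal(nrow(u), 1L)
  expect_equal(c(u$start, u$end), c(1000L, 3000L))
  expect_equal(u$method, "merged")
  # disjoint sets concatenate; identical sets collapse to themselves
  three <- mk(10000L, 11000L, "assembly")
  expect_equal(nrow(union_clusters(one, three, aln)), 2L)
  expect_equal(nrow(union_clusters(one, one, aln)), 1L)
})

test_that("common clusters use the >50%-of-shorter overlap rule", {
  mk <- function(s, e, sample) tibble::tibble(
    chrom = "chr1", start = s, end = e, n_loci = 10L, read_weight = 10,
    density = 5, strand_ratio = 1, sample = sample, method = "density")
  a <- mk(1000L, 2000L, "ovary")
  # identical clusters are common
  cc <- common_clusters(a, mk(1000L, 2000L, "testis"))
  expect_true(all(cc$clusters$sample == "common"))
  # 1000-bp and 400-bp clusters overlapping by 300 bp: 300 > 0.5 * 400
  cc2 <- common_clusters(a, mk(1700L, 2100L, "testis"))
  expect_true(all(cc2$clusters$sample == "common"))
  expect_equal(cc2$pairs$overlap, 300)
  # but not under the reciprocal rule (300 < 0.5 * 1000)
  cc2r <- common_clusters(a, mk(1700L, 2100L, "testis"), mode = "reciprocal")
  expect_equal(sort(unique(cc2r$clusters$sample)), c("ovary", "testis"))
  # zero overlap: both sample-specific
  cc3 <- common_clusters(a, mk(5000L, 6000L, "testis"))
  expect_equal(sort(unique(cc3$clusters$sample)), c("ovary", "testis"))
  expect_equal(nrow(cc3$pairs), 0L)
})

test_that("location conservation counts clusters with homologous partners", {
  mk <- function(s, e, chrom = "chr1") tibble::tibble(
    chrom = chrom, start = s, end = e, n_loci = 10L, read_weight = 10,
    density = 5, strand_ratio = 1, sample = "ovary", method = "density")
  a <- dplyr::bind_rows(lapply(0:9, function(i) mk(i * 5000L, i * 5000L + 1000L)))
  hom <- tibble::tibble(chrom_a = "chr1", chrom_b = "chr1")
  expect_equal(location_conservation(a, a, hom), 1.0)
  expect_equal(location_conservation(a, a[0, ], hom), 0.0)
  # 6 of 10 planted clusters shared
  b <- a[1:6, ]
  expect_equal(location_conservation(a, b, hom), 0.6)
  # unmapped chromosomes count as non-conserved, with a warning
  hom2 <- tibble::tibble(chrom_a = "chrX", chrom_b = "chr1")
  expect_warning(f <- location_conservation(a, a, hom2), "unmapped")
  expect_equal(f, 0.0)
})

test_that("called cluster intervals are non-overlapping within one method", {
  set.seed(23)
  aln <- aln_tbl(sort(sample.int(80000L, 500)), "+")
  cl <- detect_density(aln, min_loci = 3L)
  if (nrow(cl) > 1L) {
    cl <- dplyr::arrange(tidy(cl), start)
    expect_true(all(cl$start[-1] >= cl$end[-nrow(cl)]))
  }
  expect_true(all(cl$density == cl$n_loci / ((cl$end - cl$start) / 1000)))
})
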