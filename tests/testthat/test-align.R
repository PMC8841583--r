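test_that("mismatch-pattern rule enforces seed, 3'-terminal and budget limits", {
  expect_true(valid_mismatch_pattern(30, integer(0)))
  expect_true(valid_mismatch_pattern(30, c(19, 28)))
  expect_false(valid_mismatch_pattern(30, c(18, 28)))   # inside the 18-nt seed
  expect_false(valid_mismatch_pattern(30, 29))          # last two positions
  expect_false(valid_mismatch_pattern(30, 30))
  expect_false(valid_mismatch_pattern(30, c(19, 22, 25)))  # budget of two
  expect_true(valid_mismatch_pattern(24, c(19, 22)))
  expect_error(valid_mismatch_pattern(30, 31), "1, length")
})

test_that("alignment enumeration handles planted exact and mismatched loci", {
  set.seed(21)
  genome <- c(chr1 = rand_seq(5000))
  # a read present verbatim exactly once
  r1 <- substr(genome[["chr1"]], 1001, 1030)
  # a read whose only locus differs at position 5 (seed violation)
  r2ch <- strsplit(substr(genome[["chr1"]], 2001, 2030), "")[[1]]
  r2ch[5] <- setdiff(c("A", "C", "G", "T"), r2ch[5])[1]
  # a read differing at 20 and 25 (valid) and one at 20, 25, 27 (budget)
  r3ch <- strsplit(substr(genome[["chr1"]], 3001, 3030), "")[[1]]
  for (p in c(20L, 25L)) r3ch[p] <- setdiff(c("A", "C", "G", "T"), r3ch[p])[1]
  r4ch <- strsplit(substr(genome[["chr1"]], 4001, 4030), "")[[1]]
  for (p in c(20L, 25L, 27L)) r4ch[p] <- setdiff(c("A", "C", "G", "T"), r4ch[p])[1]
  reads <- tibble::tibble(
    id = c("exact", "seedmm", "two", "three"),
    seq = c(r1, paste(r2ch, collapse = ""), paste(r3ch, collapse = ""),
            paste(r4ch, collapse = "")),
    count = 1)
  aln <- enumerate_alignments(reads, genome)
  expect_equal(aln$start[aln$read_id == "exact"], 1000L)
  expect_equal(aln$n_mm[aln$read_id == "exact"], 0L)
  expect_false("seedmm" %in% aln$read_id)
  expect_equal(aln$mismatch_pos[aln$read_id == "two"], "20,25")
  expect_false("three" %in% aln$read_id)
})

test_that("enumeration agrees with the exhaustive sliding-window oracle", {
  set.seed(31)
  genome <- c(chrA = rand_seq(3000), chrB = rand_seq(2000))
  reads <- list()
  # plant reads on both strands with 0-2 mismatches at legal/illegal positions
  pick <- function(chrom, at, len) substr(genome[[chrom]], at, at + len - 1L)
  raw <- c(pick("chrA", 101, 28), revcomp(pick("chrA", 501, 30)),
           pick("chrB", 301, 26), revcomp(pick("chrB", 901, 24)),
           rand_seq(27))
  mutate_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  raw <- c(raw, mutate_at(raw[1], 20L), mutate_at(raw[2], c(19L, 27L)),
           mutate_at(raw[3], 25L))
  reads <- tibble::tibble(id = sprintf("r%d", seq_along(raw)), seq = raw, count = 1)
  aln <- enumerate_alignments(reads, genome) |>
    dplyr::select(read_id, chrom, start, strand, n_mm, mismatch_pos) |>
    dplyr::arrange(read_id, chrom, start, strand)
  oracle <- dplyr::bind_rows(lapply(seq_len(nrow(reads)), function(i)
    oracle_scan(reads[i, ], genome))) |>
    dplyr::arrange(read_id, chrom, start, strand)
  expect_equal(as.data.frame(aln), as.data.frame(oracle))
})

test_that("shrinking the mismatch budget never enlarges the alignment set", {
  set.seed(41)
  genome <- c(chr1 = rand_seq(4000))
  reads <- tibble::tibble(
    id = sprintf("r%d", 1:6),
    seq = vapply(1:6, function(i) {
      s <- substr(genome[["chr1"]], i * 500, i * 500 + 27)
      ch <- strsplit(s, "")[[1]]
      if (i %% 2 == 0) ch[20] <- setdiff(c("A", "C", "G", "T"), ch[20])[1]
      paste(ch, collapse = "")
    }, character(1)),
    count = 1)
  key <- function(a) paste(a$read_id, a$chrom, a$start, a$strand)
  a0 <- enumerate_alignments(reads, genome, max_mm = 0L)
  a1 <- enumerate_alignments(reads, genome, max_mm = 1L)
  a2 <- enumerate_alignments(reads, genome, max_mm = 2L)
  expect_true(all(key(a0) %in% key(a1)))
  expect_true(all(key(a1) %in% key(a2)))
})

test_that("best-stratum selection keeps exactly the minimum-mismatch ties", {
  aln <- aln_tbl(fp = c(100L, 500L, 900L), strand = "+", read_id = rep("r1", 3))
  aln$n_mm <- c(0L, 1L, 1L)
  expect_equal(nrow(select_min_mismatch(aln)), 1L)
  aln$n_mm <- c(2L, 2L, 2L)
  expect_equal(nrow(select_min_mismatch(aln)), 3L)
  expect_equal(nrow(select_min_mismatch(aln[0, ])), 0L)
})

test_that("reallocation splits counts by local unique-mapper density", {
  # one multimapper (count 4) at two loci; unique mass 30 near locus 1, 10 near locus 2
  uniq <- aln_tbl(fp = c(1000L, 50000L), strand = "+", weight = c(30, 10),
                  read_id = c("u1", "u2"))
  multi <- aln_tbl(fp = c(1200L, 50200L), strand = "+", weight = NA,
                   count = 4, read_id = c("m", "m"))
  out <- reallocate_weights(dplyr::bind_rows(uniq, multi))
  w <- out$weight[out$read_id == "m"]
  expect_equal(sort(w), c(1, 3))
  expect_equal(out$weight[out$read_id == "u1"], 30)
  # no unique mass anywhere near: uniform fallback
  lone <- aln_tbl(fp = c(200000L, 300000L), strand = "+", weight = NA,
                  count = 6, read_id = c("x", "x"))
  out2 <- reallocate_weights(dplyr::bind_rows(uniq, lone))
  expect_equal(out2$weight[out2$read_id == "x"], c(3, 3))
})

test_that("weight is conserved through mapping of multimapping libraries", {
  cfg <- sim_config(genome_length = 50000L, rng_seed = 13L, te_families = list(),
                    genes = list(),
                    clusters = list(cluster_spec(1500L, 15L, depth = 600L)),
                    multimap_copies = 2L)
  sim <- simulate_genome(cfg)
  reads <- length_filter(simulate_pirna_reads(sim)$reads)
  aln <- align_reads(reads, sim$genome)
  expect_equal(sum(aln$weight), sum(reads$count))
  # multimappers exist (cluster body duplicated twice)
  per_read <- table(aln$read_id)
  expect_true(any(per_read > 1))
  # every read's weights sum to its count
  by_read <- aln |> dplyr::group_by(read_id) |>
    dplyr::summarise(w = sum(weight), c = count[1])
  expect_equal(by_read$w, by_read$c)
})
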