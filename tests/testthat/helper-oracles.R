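# shared fixtures and brute-force oracles, built in code at test time

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# manual alignment row(s); minus-strand `fp` is the rightmost (5') base
aln_tbl <- function(fp, strand, length = 26L, weight = 1, chrom = "chr1",
                    count = weight, read_id = NULL) {
  n <- max(length(fp), length(strand))
  fp <- rep_len(fp, n); strand <- rep_len(strand, n)
  length <- rep_len(length, n); weight <- rep_len(weight, n)
  count <- rep_len(count, n)
  tibble::tibble(
    read_id = read_id %||% sprintf("m%03d", seq_len(n)),
    chrom = chrom,
    start = ifelse(strand == "+", fp, fp - length + 1L),
    strand = strand, length = as.integer(length),
    mismatch_pos = "", n_mm = 0L, count = count, weight = weight)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive sliding-window alignment scan: every offset, both strands,
# mismatch rule applied literally in read coordinates (vectorised over offsets)
oracle_scan <- function(read, genome, seed_len = 18L, max_mm = 2L,
                        protect_3p = 2L) {
  out <- list()
  L <- nchar(read$seq)
  rch <- strsplit(toupper(read$seq), "")[[1]]
  for (chrom in names(genome)) {
    gch <- strsplit(toupper(genome[[chrom]]), "")[[1]]
    G <- length(gch)
    for (strand in c("+", "-")) {
      tch <- if (strand == "+") rch else
        strsplit(pirnascape::revcomp(read$seq), "")[[1]]
      # mismatch matrix: offsets x target positions
      mat <- vapply(seq_len(L), function(j) gch[j:(G - L + j)] != tch[j],
                    logical(G - L + 1L))
      if (strand == "+") {
        seed_cols <- seq_len(seed_len); last_cols <- (L - protect_3p + 1L):L
      } else {
        seed_cols <- (L - seed_len + 1L):L; last_cols <- seq_len(protect_3p)
      }
      ok <- rowSums(mat) <= max_mm &
        rowSums(mat[, seed_cols, drop = FALSE]) == 0 &
        rowSums(mat[, last_cols, drop = FALSE]) == 0
      for (o in which(ok) - 1L) {
        mm_t <- which(mat[o + 1L, ])
        mm <- if (strand == "+") mm_t else sort(L + 1L - mm_t)
        out[[length(out) + 1L]] <- tibble::tibble(
          read_id = read$id, chrom = chrom, start = o, strand = strand,
          n_mm = length(mm),
          mismatch_pos = paste(mm, collapse = ","))
      }
    }
  }
  if (length(out) == 0L)
    return(tibble::tibble(read_id = character(), chrom = character(),
                          start = integer(), strand = character(),
                          n_mm = integer(), mismatch_pos = character()))
  dplyr::arrange(dplyr::bind_rows(out), chrom, start, strand)
}

# all-pairs quadratic overlap scorer
oracle_overlap_scores <- function(aln, max_d = 30L) {
  S <- stats::setNames(numeric(max_d), as.character(seq_len(max_d)))
  fp <- ifelse(aln$strand == "+", aln$start, aln$start + aln$length - 1L)
  for (i in seq_len(nrow(aln))) for (j in seq_len(nrow(aln))) {
    if (aln$strand[i] != "+" || aln$strand[j] != "-") next
    if (aln$chrom[i] != aln$chrom[j]) next
    d <- fp[j] - fp[i] + 1L
    if (d >= 1L && d <= max_d) S[d] <- S[d] + aln$weight[i] * aln$weight[j]
  }
  S
}

# per-base repeat-overlap assignment: lowest diversity wins each base,
# ties by earlier start then family name
oracle_perbase_resolve <- function(ann, div, genome_length) {
  owner <- rep(NA_integer_, genome_length)
  ord <- order(div[ann$family], ann$start, ann$family)
  for (i in ord) {
    idx <- (ann$start[i] + 1L):ann$end[i]
    free <- idx[is.na(owner[idx])]
    owner[free] <- i
  }
  owner
}

# flatten a category map to one label per base (for partition checks)
perbase_categories <- function(cmap, chrom, genome_length) {
  lab <- rep(NA_character_, genome_length)
  seg <- cmap[cmap$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(seg)))
    lab[(seg$start[i] + 1L):seg$end[i]] <- as.character(seg$category[i])
  lab
}

# reciprocal >50% overlap matching of predicted vs true intervals
match_clusters <- function(pred, truth, min_frac = 0.5) {
  matched_pred <- logical(nrow(pred))
  matched_truth <- logical(nrow(truth))
  for (i in seq_len(nrow(pred))) for (j in seq_len(nrow(truth))) {
    if (pred$chrom[i] != truth$chrom[j]) next
    ov <- max(0, min(pred$end[i], truth$end[j]) - max(pred$start[i], truth$start[j]))
    if (ov > min_frac * (pred$end[i] - pred$start[i]) &&
        ov > min_frac * (truth$end[j] - truth$start[j])) {
      matched_pred[i] <- TRUE; matched_truth[j] <- TRUE
    }
  }
  list(precision = mean(matched_pred), recall = mean(matched_truth))
}
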