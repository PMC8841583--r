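new_cluster_tbl <- function(x) {
  structure(as_tibble(x), class = c("pirna_clusters", class(as_tibble(x))))
}

empty_clusters <- function() {
  new_cluster_tbl(tibble(chrom = character(), start = integer(), end = integer(),
                         n_loci = integer(), read_weight = numeric(),
                         density = numeric(), strand_ratio = numeric(),
                         sample = character(), method = character()))
}

# distinct 5' loci of an alignment tibble, with summed weights
loci_table <- function(alignments) {
  alignments |>
    mutate(fp = five_prime_pos(.data$start, .data$strand, .data$length)) |>
    group_by(.data$chrom, .data$fp) |>
    summarise(w = sum(.data$weight),
              w_plus = sum(.data$weight[.data$strand == "+"]),
              .groups = "drop") |>
    arrange(.data$chrom, .data$fp)
}

annotate_cluster <- function(loci, chrom, start, end, sample, method) {
  inside <- loci$chrom == chrom & loci$fp >= start & loci$fp < end
  l <- loci[inside, , drop = FALSE]
  w <- sum(l$w)
  tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
         n_loci = nrow(l), read_weight = w,
         density = nrow(l) / ((end - start) / 1000),
         strand_ratio = if (w > 0) sum(l$w_plus) / w else NA_real_,
         sample = sample, method = method)
}

#' Call piRNA clusters by read-locus density
#'
#' Candidate regions are maximal runs of mapped 5' loci in which successive
#' loci are no more than `window` bases apart (the union of occupied
#' `window`-sized windows), trimmed to the outermost loci (the trailing locus
#' base is included).  A candidate is kept iff its locus density is at least
#' `min_density` loci/kb *and* it holds at least `min_loci` distinct loci.
#'
#' @param alignments weighted alignment tibble
#' @param window chaining window in bases (default 5000)
#' @param min_density minimum distinct-locus density in loci/kb (default 1)
#' @param min_loci minimum distinct 5' loci per cluster (default 10)
#' @param sample sample label carried on the output (e.g. "ovary", "testis")
#' @return `pirna_clusters` tibble: chrom, start, end, n_loci, read_weight,
#'   density, strand_ratio, sample, method
#' @export
detect_density <- function(alignments, window = 5000L, min_density = 1,
                           min_loci = 10L, sample = "sample") {
  if (nrow(alignments) == 0L) return(empty_clusters())
  loci <- loci_table(alignments)
  out <- list()
  for (ch in unique(loci$chrom)) {
    fp <- loci$fp[loci$chrom == ch]
    brk <- which(diff(fp) > window)
    starts <- fp[c(1L, brk + 1L)]
    ends <- fp[c(brk, length(fp))] + 1L     # half-open: include trailing base
    for (i in seq_along(starts)) {
      cl <- annotate_cluster(loci, ch, starts[i], ends[i], sample, "density")
      if (cl$density >= min_density && cl$n_loci >= min_loci)
        out[[length(out) + 1L]] <- cl
    }
  }
  if (length(out) == 0L) return(empty_clusters())
  new_cluster_tbl(bind_rows(out))
}

#' Call piRNA clusters by assembly-style interval chaining
#'
#' Two-stage transcript-assembly-like detector for narrow clusters.  Stage 1
#' chains alignment intervals separated by at most `gap` bases into fragments
#' and discards fragments shorter than `min_frag` bases.  Stage 2 merges
#' fragments separated by at most `merge_gap` bases and keeps merged clusters
#' with length >= `min_len` and summed read weight >= `min_weight`.  The
#' defaults (50/50, then 500/250/50) suit contiguous assemblies; `min_frag =
#' 150` is the variant for gap-rich assemblies.
#'
#' @param alignments weighted alignment tibble
#' @param min_frag minimum stage-1 fragment length (bases)
#' @param gap maximum within-fragment gap (bases)
#' @param min_len minimum merged-cluster length (bases)
#' @param merge_gap maximum between-fragment merge distance (bases)
#' @param min_weight minimum summed read weight of a merged cluster
#' @param sample sample label carried on the output
#' @return `pirna_clusters` tibble
#' @export
detect_assembly <- function(alignments, min_frag = 50L, gap = 50L,
                            min_len = 500L, merge_gap = 250L, min_weight = 50,
                            sample = "sample") {
  if (nrow(alignments) == 0L) return(empty_clusters())
  loci <- loci_table(alignments)
  out <- list()
  for (ch in unique(alignments$chrom)) {
    a <- alignments |> filter(.data$chrom == !!ch) |> arrange(.data$start)
    ir <- IRanges::reduce(IRanges::IRanges(start = a$start + 1L,
                                           end = a$start + a$length),
                          min.gapwidth = gap + 1L)
    frag <- ir[IRanges::width(ir) >= min_frag]
    if (length(frag) == 0L) next
    merged <- IRanges::reduce(frag, min.gapwidth = merge_gap + 1L)
    for (i in seq_along(merged)) {
      s0 <- IRanges::start(merged)[i] - 1L
      e0 <- IRanges::end(merged)[i]
      if (e0 - s0 < min_len) next
      cl <- annotate_cluster(loci, ch, s0, e0, sample, "assembly")
      if (cl$read_weight >= min_weight) out[[length(out) + 1L]] <- cl
    }
  }
  if (length(out) == 0L) return(empty_clusters())
  new_cluster_tbl(bind_rows(out))
}

#' Merge density- and assembly-detected cluster sets
#'
#' Overlapping clusters from the two detectors are merged into their union
#' interval (method `"merged"`); clusters found by only one detector pass
#' through unchanged.  Locus counts, weights and densities are recomputed on
#' merged intervals from the alignments.
#'
#' @param density_set,assembly_set `pirna_clusters` tibbles on the same genome
#' @param alignments the weighted alignments both sets were called from
#' @return `pirna_clusters` tibble
#' @export
union_clusters <- function(density_set, assembly_set, alignments) {
  both <- bind_rows(as_tibble(density_set), as_tibble(assembly_set))
  if (nrow(both) == 0L) return(empty_clusters())
  loci <- loci_table(alignments)
  out <- list()
  for (ch in unique(both$chrom)) {
    b <- filter(both, .data$chrom == !!ch)
    ir <- IRanges::IRanges(start = b$start + 1L, end = b$end)
    red <- IRanges::reduce(ir)
    hits <- IRanges::findOverlaps(ir, red)
    n_src <- table(factor(S4Vectors::subjectHits(hits), levels = seq_along(red)))
    meth_of <- function(i) {
      src <- b$method[S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == i]]
      if (length(unique(src)) > 1L) "merged" else unique(src)
    }
    for (i in seq_along(red)) {
      cl <- annotate_cluster(loci, ch, IRanges::start(red)[i] - 1L,
                             IRanges::end(red)[i], b$sample[1], meth_of(i))
      out[[length(out) + 1L]] <- cl
    }
  }
  new_cluster_tbl(bind_rows(out))
}

#' Label clusters common to or specific to two samples
#'
#' A cluster pair (one from each sample) is *common* iff their overlap exceeds
#' `min_frac` of the shorter cluster's length (`mode = "shorter"`, the
#' permissive reading of "more than half of the overlapped sequences"), or of
#' both lengths (`mode = "reciprocal"`).  Unpaired clusters are labelled with
#' their sample of origin.
#'
#' @param set_a,set_b `pirna_clusters` tibbles for the two samples
#' @param min_frac overlap fraction threshold (default 0.5, strictly exceeded)
#' @param mode `"shorter"` or `"reciprocal"`
#' @return list with `clusters` (both sets, `sample` relabelled "common" where
#'   paired) and `pairs` (tibble of common pairs with both intervals and
#'   overlap length)
#' @export
common_clusters <- function(set_a, set_b, min_frac = 0.5,
                            mode = c("shorter", "reciprocal")) {
  mode <- match.arg(mode)
  a <- as_tibble(set_a); b <- as_tibble(set_b)
  pairs <- list()
  common_a <- logical(nrow(a)); common_b <- logical(nrow(b))
  if (nrow(a) && nrow(b)) for (i in seq_len(nrow(a))) {
    j_ch <- which(b$chrom == a$chrom[i])
    for (j in j_ch) {
      ov <- overlap_len(a$start[i], a$end[i], b$start[j], b$end[j])
      la <- a$end[i] - a$start[i]; lb <- b$end[j] - b$start[j]
      ok <- if (mode == "shorter") ov > min_frac * min(la, lb)
            else ov > min_frac * la && ov > min_frac * lb
      if (ok) {
        common_a[i] <- TRUE; common_b[j] <- TRUE
        pairs[[length(pairs) + 1L]] <- tibble(
          chrom = a$chrom[i], start_a = a$start[i], end_a = a$end[i],
          start_b = b$start[j], end_b = b$end[j], overlap = ov)
      }
    }
  }
  a$sample[common_a] <- "common"
  b$sample[common_b] <- "common"
  list(clusters = new_cluster_tbl(bind_rows(a, b)),
       pairs = if (length(pairs)) bind_rows(pairs) else
         tibble(chrom = character(), start_a = integer(), end_a = integer(),
                start_b = integer(), end_b = integer(), overlap = integer()))
}

#' Fraction of clusters conserved at homologous locations
#'
#' Maps each cluster of `set_a` through a chromosome homology map (paired
#' chromosome names with an optional affine coordinate transform) and reports
#' the fraction with at least one overlapping cluster in `set_b`.  Clusters on
#' unmapped chromosomes count as non-conserved (with a warning).
#'
#' @param set_a,set_b `pirna_clusters` tibbles from the two (sub)genomes
#' @param homology_map tibble: chrom_a, chrom_b, and optional `scale`,
#'   `offset` (b = a * scale + offset; default identity)
#' @return conservation fraction in `[0, 1]`
#' @export
location_conservation <- function(set_a, set_b, homology_map) {
  a <- as_tibble(set_a); b <- as_tibble(set_b)
  if (nrow(a) == 0L) return(NA_real_)
  if (!"scale" %in% names(homology_map)) homology_map$scale <- 1
  if (!"offset" %in% names(homology_map)) homology_map$offset <- 0
  n_unmapped <- 0L
  hit <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    m <- homology_map[homology_map$chrom_a == a$chrom[i], , drop = FALSE]
    if (nrow(m) == 0L) { n_unmapped <- n_unmapped + 1L; next }
    s <- a$start[i] * m$scale[1] + m$offset[1]
    e <- a$end[i] * m$scale[1] + m$offset[1]
    cand <- b[b$chrom == m$chrom_b[1], , drop = FALSE]
    hit[i] <- any(overlap_len(s, e, cand$start, cand$end) > 0)
  }
  if (n_unmapped > 0L)
    warn(sprintf("%d clusters on unmapped chromosomes counted as non-conserved",
                 n_unmapped))
  mean(hit)
}

#' @method glance pirna_clusters
#' @export
glance.pirna_clusters <- function(x, ...) {
  tibble(n_clusters = nrow(x), total_span = sum(x$end - x$start),
         mean_density = mean(x$density), total_weight = sum(x$read_weight))
}

#' @method tidy pirna_clusters
#' @export
tidy.pirna_clusters <- function(x, ...) as_tibble(x)

#' Plot called piRNA clusters along the genome
#' @param object a `pirna_clusters`
#' @param ... ignored
#' @return a ggplot
#' @method autoplot pirna_clusters
#' @export
autoplot.pirna_clusters <- function(object, ...) {
  dat <- as_tibble(object)
  ggplot2::ggplot(dat) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$chrom, yend = .data$chrom,
                                       colour = .data$sample),
                          linewidth = 4) +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
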