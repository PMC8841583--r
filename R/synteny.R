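#' Flanking-exon anchors of a piRNA cluster
#'
#' Collects the `n` nearest exons upstream and downstream of a cluster (fewer
#' near chromosome ends) together with their genomic sequences, for use as
#' synteny anchors.  Only clusters longer than `min_cluster_len` (default
#' 1 kb) are eligible.
#'
#' @param cluster one-row tibble with chrom, start, end and a cluster id column
#'   (`cluster_id`)
#' @param genes gene annotation tibble with exon rows (`feature == "exon"`)
#' @param genome named character vector of chromosome sequences
#' @param n exons per side (default 10)
#' @param min_cluster_len minimum cluster length in bases (default 1000,
#'   strictly exceeded)
#' @return `synteny_anchor` tibble: cluster_id, side ("up"/"down"), rank
#'   (1 = nearest), chrom, start, end, seq; zero rows (with a warning) when the
#'   chromosome has no exons
#' @export
flanking_exons <- function(cluster, genes, genome, n = 10L,
                           min_cluster_len = 1000L) {
  stopifnot(nrow(cluster) == 1L)
  if (cluster$end - cluster$start <= min_cluster_len)
    abort(sprintf("cluster %s is not longer than %d bp; excluded from synteny analysis",
                  cluster$cluster_id, min_cluster_len))
  ex <- genes |>
    filter(.data$feature == "exon", .data$chrom == cluster$chrom) |>
    arrange(.data$start)
  empty <- tibble(cluster_id = character(), side = character(), rank = integer(),
                  chrom = character(), start = integer(), end = integer(),
                  seq = character())
  if (nrow(ex) == 0L) {
    warn(sprintf("no exons on %s: empty anchor for %s",
                 cluster$chrom, cluster$cluster_id))
    return(structure(empty, class = c("synteny_anchor", class(empty))))
  }
  up <- ex |> filter(.data$end <= cluster$start) |>
    arrange(desc(.data$end)) |> head(n) |>
    mutate(side = "up", rank = row_number())
  down <- ex |> filter(.data$start >= cluster$end) |>
    arrange(.data$start) |> head(n) |>
    mutate(side = "down", rank = row_number())
  anchor <- bind_rows(up, down)
  if (nrow(anchor) == 0L) {
    warn(sprintf("no flanking exons for %s", cluster$cluster_id))
    return(structure(empty, class = c("synteny_anchor", class(empty))))
  }
  gch <- genome[[cluster$chrom]]
  anchor <- anchor |>
    mutate(cluster_id = cluster$cluster_id,
           seq = substr(rep(gch, dplyr::n()), .data$start + 1L, .data$end)) |>
    select("cluster_id", "side", "rank", "chrom", "start", "end", "seq") |>
    arrange(.data$start)
  structure(anchor, class = c("synteny_anchor", class(anchor)))
}

#' Seeded local similarity search against a genome
#'
#' A k-mer-seeded, banded local search: exact k-mer seeds of the query are
#' located in each target chromosome (both strands), clustered into diagonal
#' bands, and each band is rescored with a Smith-Waterman local alignment
#' under a fixed scheme (match +1, mismatch -2, gap open -5, gap extend -2 by
#' default).  Hits whose aligned query span is shorter than `min_rel_size`
#' times the query length are discarded.
#'
#' @param query DNA string (non-empty)
#' @param target named character vector of chromosome sequences
#' @param min_rel_size minimum aligned-query-span / query-length (default 0.10)
#' @param k seed length (default 12)
#' @param step seed sampling stride along the query (default 4)
#' @param match,mismatch,gap_open,gap_ext scoring scheme
#' @return tibble of hits: chrom, t_start, t_end (0-based half-open), strand,
#'   score, identity, q_start, q_end (1-based query coords), q_span
#' @export
local_similarity_search <- function(query, target, min_rel_size = 0.10,
                                    k = 12L, step = 4L, match = 1,
                                    mismatch = -2, gap_open = 5, gap_ext = 2) {
  if (!nzchar(query)) abort("`query` must be non-empty")
  query <- toupper(chartr("U", "T", query))
  nq <- nchar(query)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                     mismatch = mismatch,
                                                     baseOnly = TRUE)
  hits <- list()
  for (strand in c("+", "-")) {
    qseq <- if (strand == "+") query else revcomp(query)
    if (nq < k) next
    qpos <- unique(c(seq(1L, nq - k + 1L, by = step), nq - k + 1L))
    kmers <- substr(rep(qseq, length(qpos)), qpos, qpos + k - 1L)
    keep <- !grepl("[^ACGT]", kmers)
    if (!any(keep)) next
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers[keep]))
    qk <- qpos[keep]
    for (ch in names(target)) {
      subj <- Biostrings::DNAString(target[[ch]])
      G <- length(subj)
      mi <- Biostrings::startIndex(Biostrings::matchPDict(pd, subj))
      seed <- bind_rows(lapply(seq_along(mi), function(i) {
        if (length(mi[[i]]) == 0L) return(NULL)
        tibble(q = qk[i], t = mi[[i]])
      }))
      if (is.null(seed) || nrow(seed) == 0L) next
      seed <- seed |> mutate(diag = .data$t - .data$q) |> arrange(.data$diag, .data$t)
      band <- cumsum(c(1L, diff(seed$diag) > 40L | diff(seed$t) > 5000L))
      for (bi in unique(band)) {
        s <- seed[band == bi, , drop = FALSE]
        ws <- max(1L, min(s$t) - min(s$q) - 30L)
        we <- min(G, max(s$t) + k - 1L + (nq - max(s$q)) + 30L)
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(qseq), Biostrings::subseq(subj, ws, we),
          type = "local", substitutionMatrix = submat,
          gapOpening = gap_open, gapExtension = gap_ext)
        sc <- Biostrings::score(pa)
        if (sc <= 0) next
        prng <- pa@pattern@range
        srng <- pa@subject@range
        qa <- IRanges::start(prng); qb <- IRanges::end(prng)
        if (strand == "-") { tmp <- qa; qa <- nq - qb + 1L; qb <- nq - tmp + 1L }
        aln_len <- Biostrings::nchar(pa)
        hits[[length(hits) + 1L]] <- tibble(
          chrom = ch,
          t_start = ws + IRanges::start(srng) - 2L,   # 0-based
          t_end = ws + IRanges::end(srng) - 1L,
          strand = strand, score = sc,
          identity = Biostrings::nmatch(pa) / aln_len,
          q_start = qa, q_end = qb, q_span = qb - qa + 1L)
      }
    }
  }
  if (length(hits) == 0L)
    return(tibble(chrom = character(), t_start = integer(), t_end = integer(),
                  strand = character(), score = numeric(), identity = numeric(),
                  q_start = integer(), q_end = integer(), q_span = integer()))
  out <- bind_rows(hits) |>
    filter(.data$q_span >= min_rel_size * nq) |>
    arrange(desc(.data$score))
  # drop near-duplicate hits from adjacent bands (same strand, overlapping target)
  if (nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    for (i in 2:nrow(out)) {
      prior <- which(keep[seq_len(i - 1L)])
      same <- out$chrom[prior] == out$chrom[i] & out$strand[prior] == out$strand[i]
      if (any(same & overlap_len(out$t_start[prior], out$t_end[prior],
                                 out$t_start[i], out$t_end[i]) > 0))
        keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Group per-exon hits into candidate syntenic regions
#'
#' Takes the best hit of each anchor exon, sorts hits by target position per
#' chromosome, and chains hits separated by at most `max_span` bases into
#' groups.  A group is flagged collinear when the target order of its hits
#' matches the exons' genomic order (forward or reverse).
#'
#' @param exon_hits tibble with one best hit per exon: exon_order (genomic
#'   order index), chrom, t_start, t_end, score
#' @param max_span maximum span between neighbouring hits in a group (default
#'   1e6 bases)
#' @return tibble: group_id, chrom, t_start, t_end, n_exons, total_score,
#'   collinear
#' @export
group_hits <- function(exon_hits, max_span = 1e6) {
  if (nrow(exon_hits) == 0L)
    return(tibble(group_id = integer(), chrom = character(), t_start = integer(),
                  t_end = integer(), n_exons = integer(), total_score = numeric(),
                  collinear = logical()))
  out <- list()
  gid <- 0L
  for (ch in unique(exon_hits$chrom)) {
    h <- exon_hits |> filter(.data$chrom == !!ch) |> arrange(.data$t_start)
    grp <- cumsum(c(1L, diff(h$t_start) > max_span))
    for (g in unique(grp)) {
      s <- h[grp == g, , drop = FALSE]
      gid <- gid + 1L
      ord <- s$exon_order[order(s$t_start)]
      out[[gid]] <- tibble(
        group_id = gid, chrom = ch, t_start = min(s$t_start),
        t_end = max(s$t_end), n_exons = dplyr::n_distinct(s$exon_order),
        total_score = sum(s$score),
        collinear = all(diff(ord) >= 0) || all(diff(ord) <= 0))
    }
  }
  bind_rows(out)
}

#' Call synteny of a piRNA cluster against a second genome
#'
#' Searches each anchor exon against the target genome, keeps the best hit
#' per exon, groups hits into candidate regions, and calls the cluster
#' syntenic iff a single region holds at least `min_exons` homologous anchor
#' exons ("more than three homologous exons" read strictly as >= 4).  The call
#' also reports whether a target-genome cluster lies in or near the matched
#' region, and whether the cluster body sequence itself has a surviving hit
#' there (`cluster_body_conserved`).
#'
#' @param anchor a `synteny_anchor` from [flanking_exons()]
#' @param target named character vector: the second genome
#' @param cluster_seq optional DNA string of the cluster body
#' @param target_clusters optional cluster tibble (chrom, start, end) for the
#'   target genome
#' @param min_exons homologous-exon threshold (default 4)
#' @param min_rel_size hit-length filter passed to
#'   [local_similarity_search()]
#' @param max_span grouping span, see [group_hits()]
#' @param pad slack in bases when intersecting the matched region with target
#'   clusters and body hits (default 20000)
#' @return one-row `synteny_call` tibble: cluster_id, syntenic,
#'   n_homologous_exons, total_bit_score, chrom_b, region_start, region_end,
#'   collinear, cluster_nearby, cluster_body_conserved
#' @export
call_synteny <- function(anchor, target, cluster_seq = NULL,
                         target_clusters = NULL, min_exons = 4L,
                         min_rel_size = 0.10, max_span = 1e6, pad = 20000) {
  cid <- if (nrow(anchor) > 0L) anchor$cluster_id[1] else NA_character_
  mk <- function(syntenic, n_ex = 0L, score = 0, chrom_b = NA_character_,
                 rs = NA_integer_, re = NA_integer_, col = NA,
                 nearby = NA, body = NA) {
    out <- tibble(cluster_id = cid, syntenic = syntenic,
                  n_homologous_exons = n_ex, total_bit_score = score,
                  chrom_b = chrom_b, region_start = rs, region_end = re,
                  collinear = col, cluster_nearby = nearby,
                  cluster_body_conserved = body)
    structure(out, class = c("synteny_call", class(out)))
  }
  if (nrow(anchor) == 0L) {
    warn("empty anchor: cluster called non-syntenic")
    return(mk(FALSE))
  }
  best <- list()
  for (i in seq_len(nrow(anchor))) {
    h <- local_similarity_search(anchor$seq[i], target, min_rel_size = min_rel_size)
    if (nrow(h) == 0L) next
    best[[length(best) + 1L]] <- mutate(h[1, ], exon_order = i)
  }
  if (length(best) == 0L) return(mk(FALSE))
  groups <- group_hits(bind_rows(best), max_span = max_span)
  top <- groups |> arrange(desc(.data$n_exons), desc(.data$total_score)) |> head(1)
  syntenic <- top$n_exons >= min_exons
  nearby <- NA
  body <- NA
  if (!is.null(target_clusters)) {
    tc <- target_clusters[target_clusters$chrom == top$chrom, , drop = FALSE]
    nearby <- any(overlap_len(top$t_start - pad, top$t_end + pad,
                              tc$start, tc$end) > 0)
  }
  if (!is.null(cluster_seq)) {
    bh <- local_similarity_search(cluster_seq, target, min_rel_size = min_rel_size)
    body <- if (nrow(bh) == 0L) FALSE else any(
      bh$chrom == top$chrom &
        overlap_len(top$t_start - pad, top$t_end + pad, bh$t_start, bh$t_end) > 0)
  }
  mk(syntenic, top$n_exons, top$total_score, top$chrom, top$t_start, top$t_end,
     top$collinear, nearby, body)
}

#' Screen all piRNA clusters of one genome for synteny in another
#'
#' Applies [flanking_exons()] and [call_synteny()] to every cluster longer
#' than `min_cluster_len`, extracting cluster body sequences from the source
#' genome.  Shorter clusters are skipped (reported with `eligible = FALSE`).
#'
#' @param clusters cluster tibble for genome A (chrom, start, end, cluster_id)
#' @param genes gene annotation of genome A (exon rows used)
#' @param genome_a,genome_b named character vectors of the two genomes
#' @param clusters_b optional cluster tibble of genome B
#' @param n_flank exons per side (default 10)
#' @param min_exons homologous-exon threshold (default 4)
#' @param min_cluster_len eligibility cutoff (default 1000, strictly exceeded)
#' @param ... passed to [call_synteny()]
#' @return tibble of per-cluster calls with an `eligible` column
#' @export
synteny_screen <- function(clusters, genes, genome_a, genome_b,
                           clusters_b = NULL, n_flank = 10L, min_exons = 4L,
                           min_cluster_len = 1000L, ...) {
  out <- list()
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, , drop = FALSE]
    if (cl$end - cl$start <= min_cluster_len) {
      out[[i]] <- tibble(cluster_id = cl$cluster_id, eligible = FALSE,
                         syntenic = NA)
      next
    }
    anchor <- flanking_exons(cl, genes, genome_a, n = n_flank,
                             min_cluster_len = min_cluster_len)
    body <- substr(genome_a[[cl$chrom]], cl$start + 1L, cl$end)
    call <- call_synteny(anchor, genome_b, cluster_seq = body,
                         target_clusters = clusters_b, min_exons = min_exons, ...)
    out[[i]] <- mutate(call, eligible = TRUE)
  }
  bind_rows(out)
}
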