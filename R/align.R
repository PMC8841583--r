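#' Validate a read's mismatch pattern against the seed/terminal rule
#'
#' An alignment is acceptable iff it has (a) no mismatch within the 5' seed
#' (positions 1..`seed_len`), (b) no mismatch in the last `protect_3p`
#' positions, and (c) at most `max_mm` mismatches in total.  Positions are
#' 1-based from the read's 5' end.
#'
#' @param length read length in nt
#' @param mismatch_positions integer vector of mismatch positions (may be empty)
#' @param seed_len seed length (default 18)
#' @param max_mm mismatch budget outside the protected areas (default 2)
#' @param protect_3p protected 3'-terminal positions (default 2)
#' @return logical scalar
#' @export
#' @examples
#' valid_mismatch_pattern(30, integer(0))   # TRUE
#' valid_mismatch_pattern(30, c(19, 28))    # TRUE
#' valid_mismatch_pattern(30, c(18, 28))    # FALSE: inside the seed
#' valid_mismatch_pattern(30, 29)           # FALSE: last two positions
valid_mismatch_pattern <- function(length, mismatch_positions,
                                   seed_len = 18L, max_mm = 2L, protect_3p = 2L) {
  mp <- as.integer(mismatch_positions)
  if (any(mp < 1L | mp > length)) abort("mismatch positions must lie in [1, length]")
  length(mp) <= max_mm &&
    !any(mp <= seed_len) &&
    !any(mp > length - protect_3p)
}

#' Enumerate all valid genomic alignments of candidate piRNA reads
#'
#' Finds, on both strands, every genomic occurrence of each read that passes
#' [valid_mismatch_pattern()]: an exact 5' seed (default 18 nt), up to `max_mm`
#' mismatches in the variable region, and no mismatch in the last `protect_3p`
#' positions.  Seed hits are located with a Biostrings dictionary match and
#' extended/verified in read coordinates.  Reads shorter than
#' `seed_len + protect_3p + 1` cannot satisfy the rule and are dropped with a
#' warning.
#'
#' @param reads tibble with `id`, `seq`, `count`
#' @param genome named character vector of chromosome sequences
#' @param seed_len,max_mm,protect_3p rule parameters, see
#'   [valid_mismatch_pattern()]
#' @return alignment tibble: read_id, chrom, start (0-based leftmost), strand,
#'   length, mismatch_pos (comma-separated, 1-based from read 5'), n_mm, count,
#'   weight (initialised to NA until [reallocate_weights()])
#' @export
enumerate_alignments <- function(reads, genome, seed_len = 18L, max_mm = 2L,
                                 protect_3p = 2L) {
  stopifnot(all(c("id", "seq", "count") %in% names(reads)))
  reads <- as_tibble(reads)
  reads$seq <- toupper(chartr("U", "T", reads$seq))
  min_len <- seed_len + protect_3p + 1L
  short <- nchar(reads$seq) < min_len
  if (any(short)) {
    warn(sprintf("%d reads shorter than %d nt cannot satisfy the mismatch rule; dropped",
                 sum(short), min_len))
    reads <- reads[!short, , drop = FALSE]
  }
  if (nrow(reads) == 0L) return(empty_alignments())

  n <- nrow(reads)
  lens <- nchar(reads$seq)
  read_chars <- strsplit(reads$seq, "", fixed = TRUE)
  rc_seqs <- revcomp(reads$seq)
  rc_chars <- strsplit(rc_seqs, "", fixed = TRUE)
  seeds_plus <- substr(reads$seq, 1L, seed_len)
  # the read's 5' seed sits at the 3' (rightmost) end of its reverse complement
  seeds_minus <- substr(rc_seqs, lens - seed_len + 1L, lens)
  pd_plus <- Biostrings::PDict(Biostrings::DNAStringSet(seeds_plus))
  pd_minus <- Biostrings::PDict(Biostrings::DNAStringSet(seeds_minus))

  out <- vector("list", length(genome) * 2L)
  k <- 0L
  for (chrom in names(genome)) {
    subject <- Biostrings::DNAString(genome[[chrom]])
    gch <- seq_chars(genome[[chrom]])
    G <- length(gch)

    hits_plus <- Biostrings::startIndex(Biostrings::matchPDict(pd_plus, subject))
    hits_minus <- Biostrings::startIndex(Biostrings::matchPDict(pd_minus, subject))

    rows <- list()
    for (i in seq_len(n)) {
      L <- lens[i]
      hp <- hits_plus[[i]]
      for (h in hp) {                     # 1-based seed start == read start
        if (h + L - 1L > G) next
        tail_idx <- (seed_len + 1L):L
        mm <- tail_idx[read_chars[[i]][tail_idx] != gch[h - 1L + tail_idx]]
        if (valid_mismatch_pattern(L, mm, seed_len, max_mm, protect_3p)) {
          rows[[length(rows) + 1L]] <- list(reads$id[i], h - 1L, "+", L,
                                            paste(mm, collapse = ","),
                                            length(mm), reads$count[i])
        }
      }
      hm <- hits_minus[[i]]
      for (h in hm) {                     # seed occupies rc positions L-17..L
        g0 <- h - (L - seed_len)          # 1-based start of the rc on the genome
        if (g0 < 1L) next
        head_idx <- seq_len(L - seed_len)
        mm_rc <- head_idx[rc_chars[[i]][head_idx] != gch[g0 - 1L + head_idx]]
        mm <- sort(L + 1L - mm_rc)        # map to read coordinates (5'->3')
        if (valid_mismatch_pattern(L, mm, seed_len, max_mm, protect_3p)) {
          rows[[length(rows) + 1L]] <- list(reads$id[i], g0 - 1L, "-", L,
                                            paste(mm, collapse = ","),
                                            length(mm), reads$count[i])
        }
      }
    }
    k <- k + 1L
    out[[k]] <- if (length(rows)) tibble(
      read_id = vapply(rows, `[[`, character(1), 1L),
      chrom = chrom,
      start = vapply(rows, `[[`, integer(1), 2L),
      strand = vapply(rows, `[[`, character(1), 3L),
      length = vapply(rows, `[[`, integer(1), 4L),
      mismatch_pos = vapply(rows, `[[`, character(1), 5L),
      n_mm = vapply(rows, `[[`, integer(1), 6L),
      count = vapply(rows, `[[`, numeric(1), 7L)) else NULL
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) return(empty_alignments())
  res$weight <- NA_real_
  arrange(res, .data$read_id, .data$chrom, .data$start, .data$strand)
}

#' Keep each read's minimum-mismatch alignment stratum
#'
#' For every read, retains the subset of its alignments whose mismatch count
#' equals the minimum over all of that read's alignments (the best stratum);
#' ties are all kept, ordered by (chrom, start, strand), and resolved
#' downstream by weight reallocation.
#'
#' @param alignments alignment tibble from [enumerate_alignments()]
#' @return alignment tibble restricted to best strata
#' @export
select_min_mismatch <- function(alignments) {
  if (nrow(alignments) == 0L) return(alignments)
  alignments |>
    group_by(.data$read_id) |>
    filter(.data$n_mm == min(.data$n_mm)) |>
    ungroup() |>
    arrange(.data$read_id, .data$chrom, .data$start, .data$strand)
}

#' Reallocate multimapper counts by local unique-mapper density
#'
#' Uniquely-mapping reads receive `weight = count`.  A read retained at
#' several loci has its count split across them in proportion to
#' `U(locus)`, the total count of uniquely-mapped reads whose 5' ends lie
#' within `window / 2` bases of the locus 5' end; if `U = 0` at every locus
#' the count is split uniformly.  Per read, weights sum to the count exactly.
#'
#' @param alignments best-stratum alignment tibble (after
#'   [select_min_mismatch()])
#' @param window total window size in bases (default 10000, i.e. +/- 5 kb)
#' @return alignment tibble with the `weight` column filled
#' @export
reallocate_weights <- function(alignments, window = 10000L) {
  if (nrow(alignments) == 0L) return(alignments)
  half <- window / 2
  aln <- alignments |>
    mutate(fp = five_prime_pos(.data$start, .data$strand, .data$length)) |>
    group_by(.data$read_id) |>
    mutate(n_loci = dplyr::n()) |>
    ungroup()
  uniq <- filter(aln, .data$n_loci == 1L)
  # per-chromosome sorted unique 5' positions for windowed density queries
  udens <- split(uniq[c("fp", "count")], uniq$chrom)
  udens <- lapply(udens, function(d) {
    d <- d[order(d$fp), ]
    list(fp = d$fp, cum = cumsum(d$count))
  })
  u_at <- function(chrom, fp) {
    d <- udens[[chrom]]
    if (is.null(d)) return(rep(0, length(fp)))
    cum0 <- c(0, d$cum)
    cum0[findInterval(fp + half, d$fp) + 1L] -
      cum0[findInterval(fp - half - 1e-9, d$fp) + 1L]
  }
  aln$U <- 0
  for (chrom in unique(aln$chrom)) {
    idx <- which(aln$chrom == chrom)
    aln$U[idx] <- u_at(chrom, aln$fp[idx])
  }
  aln <- aln |>
    group_by(.data$read_id) |>
    mutate(weight = if (dplyr::n() == 1L) .data$count
           else if (sum(.data$U) == 0) .data$count / dplyr::n()
           else .data$count * .data$U / sum(.data$U)) |>
    ungroup()
  aln |> select(-"fp", -"n_loci", -"U")
}

#' Map candidate piRNA reads: enumerate, select best stratum, reallocate
#'
#' One-call wrapper running [enumerate_alignments()],
#' [select_min_mismatch()] and [reallocate_weights()].
#'
#' @inheritParams enumerate_alignments
#' @param window reallocation window, see [reallocate_weights()]
#' @return weighted alignment tibble
#' @export
align_reads <- function(reads, genome, seed_len = 18L, max_mm = 2L,
                        protect_3p = 2L, window = 10000L) {
  reads |>
    enumerate_alignments(genome, seed_len, max_mm, protect_3p) |>
    select_min_mismatch() |>
    reallocate_weights(window)
}
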