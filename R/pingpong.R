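#' Ping-pong 5' overlap scores
#'
#' For every pair of a plus-strand alignment with 5' genomic position `p` and a
#' minus-strand alignment with 5' position `q >= p` on the same chromosome, the
#' overlap length is `d = q - p + 1` (the number of 5'-anchored overlapping
#' bases; an exact ping-pong pair scores `d = 10`).  For `1 <= d <= max_d` the
#' pair contributes the product of the two alignment weights to `S_d`.
#' Pairs are enumerated via 5'-position weight tables per chromosome, not all
#' read pairs, so the cost is linear in distinct 5' positions.
#'
#' @param alignments weighted alignment tibble (needs chrom, start, strand,
#'   length, weight)
#' @param max_d largest overlap length scored (default 30)
#' @return numeric vector `S` of length `max_d` (names "1".."max_d")
#' @export
overlap_scores <- function(alignments, max_d = 30L) {
  S <- setNames(numeric(max_d), as.character(seq_len(max_d)))
  if (nrow(alignments) == 0L) return(S)
  aln <- mutate(alignments,
                fp = five_prime_pos(.data$start, .data$strand, .data$length))
  for (chrom in unique(aln$chrom)) {
    a <- filter(aln, .data$chrom == !!chrom)
    plus <- a |> filter(.data$strand == "+") |>
      group_by(.data$fp) |> summarise(w = sum(.data$weight), .groups = "drop")
    minus <- a |> filter(.data$strand == "-") |>
      group_by(.data$fp) |> summarise(w = sum(.data$weight), .groups = "drop")
    if (nrow(plus) == 0L || nrow(minus) == 0L) next
    mw <- setNames(minus$w, as.character(minus$fp))
    for (d in seq_len(max_d)) {
      hit <- mw[as.character(plus$fp + d - 1L)]
      ok <- !is.na(hit)
      if (any(ok)) S[d] <- S[d] + sum(plus$w[ok] * hit[ok])
    }
  }
  S
}

#' Z-scores of the overlap-length profile
#'
#' Converts overlap scores to ratios `r_d = S_d / sum(S)` and standardises
#' them with the mean and *population* standard deviation over
#' `d = 1..length(S)`: `z_d = (r_d - mean(r)) / sd_pop(r)`.  If all scores are
#' zero or identical, all z are 0 by convention.  The value at `d = 10` is the
#' ping-pong signature Z-score.
#'
#' @param S numeric vector of overlap scores
#' @return numeric vector of z-scores, same length and names as `S`
#' @export
pp_zscores <- function(S) {
  D <- length(S)
  if (D < 2L) abort("need at least two overlap lengths")
  tot <- sum(S)
  if (tot == 0) return(setNames(numeric(D), names(S)))
  r <- S / tot
  sd_pop <- sqrt(mean((r - mean(r))^2))
  if (sd_pop == 0) return(setNames(numeric(D), names(S)))
  (r - mean(r)) / sd_pop
}

#' Ping-pong profile of a weighted alignment set
#'
#' Computes overlap scores, ratios and z-scores for overlap lengths
#' `1..max_d`, returned as a tidy tibble of class `pp_profile`.
#'
#' @inheritParams overlap_scores
#' @return `pp_profile` tibble: d, score, ratio, z
#' @export
pingpong_profile <- function(alignments, max_d = 30L) {
  S <- overlap_scores(alignments, max_d)
  tot <- sum(S)
  out <- tibble(d = seq_len(max_d), score = unname(S),
                ratio = if (tot > 0) unname(S) / tot else rep(0, max_d),
                z = unname(pp_zscores(S)))
  structure(out, class = c("pp_profile", class(out)))
}

#' @method glance pp_profile
#' @export
glance.pp_profile <- function(x, ...) {
  tibble(z10 = x$z[x$d == 10L],
         peak_d = x$d[which.max(x$score)],
         total_score = sum(x$score))
}

#' @method tidy pp_profile
#' @export
tidy.pp_profile <- function(x, ...) as_tibble(x)

#' Plot a ping-pong overlap profile
#' @param object a `pp_profile`
#' @param stat which column to plot, `"z"` or `"ratio"`
#' @param ... ignored
#' @return a ggplot
#' @method autoplot pp_profile
#' @export
autoplot.pp_profile <- function(object, stat = c("z", "ratio"), ...) {
  stat <- match.arg(stat)
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$d, y = .data[[stat]])) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_vline(xintercept = 10, linetype = 2, colour = "red") +
    ggplot2::labs(x = "5' overlap length (nt)",
                  y = if (stat == "z") "Z-score" else "overlap-score ratio") +
    ggplot2::theme_minimal()
}

#' 5'-end base composition (1U/10A bias) of mapped piRNAs
#'
#' Extracts the first 10 bases of each aligned read from the genome in read
#' orientation (minus-strand alignments reverse-complemented) and accumulates
#' weight-weighted base frequencies per position.  Alignments running off a
#' chromosome end are skipped and counted.
#'
#' @param alignments weighted alignment tibble
#' @param genome named character vector of chromosome sequences
#' @param n_pos positions from the 5' end to profile (default 10)
#' @return `base_bias` tibble (position, base, freq) with attributes
#'   `u1` (position-1 U frequency), `a10` (position-`n_pos` A frequency) and
#'   `n_skipped`
#' @export
base_bias <- function(alignments, genome, n_pos = 10L) {
  if (nrow(alignments) == 0L) abort("empty alignment set: no base bias to profile")
  freq <- matrix(0, nrow = n_pos, ncol = 4L, dimnames = list(NULL, DNA_BASES))
  n_skipped <- 0L
  for (chrom in unique(alignments$chrom)) {
    gch <- seq_chars(genome[[chrom]])
    G <- length(gch)
    a <- filter(alignments, .data$chrom == !!chrom)
    for (i in seq_len(nrow(a))) {
      fp <- five_prime_pos(a$start[i], a$strand[i], a$length[i])
      if (a$strand[i] == "+") {
        if (fp + n_pos > G) { n_skipped <- n_skipped + 1L; next }
        b <- gch[(fp + 1L):(fp + n_pos)]
      } else {
        if (fp - n_pos + 1L < 0L) { n_skipped <- n_skipped + 1L; next }
        b <- seq_chars(revcomp(paste(gch[(fp - n_pos + 2L):(fp + 1L)], collapse = "")))
      }
      for (p in seq_len(n_pos)) {
        if (b[p] %in% DNA_BASES) freq[p, b[p]] <- freq[p, b[p]] + a$weight[i]
      }
    }
  }
  if (n_skipped > 0L)
    warn(sprintf("%d alignments ran off a chromosome end and were skipped", n_skipped))
  rs <- rowSums(freq)
  if (all(rs == 0)) abort("no usable alignments for base bias")
  freq <- freq / rs
  out <- as_tibble(as.data.frame(freq)) |>
    mutate(position = seq_len(n_pos)) |>
    tidyr::pivot_longer(dplyr::all_of(DNA_BASES), names_to = "base",
                        values_to = "freq") |>
    select("position", "base", "freq")
  structure(out, class = c("base_bias", class(out)),
            u1 = unname(freq[1L, "T"]), a10 = unname(freq[n_pos, "A"]),
            n_skipped = n_skipped)
}

#' @method glance base_bias
#' @export
glance.base_bias <- function(x, ...) {
  tibble(u1 = attr(x, "u1"), a10 = attr(x, "a10"),
         n_skipped = attr(x, "n_skipped"))
}

#' @method tidy base_bias
#' @export
tidy.base_bias <- function(x, ...) as_tibble(x)

#' Plot the 5'-end base-frequency profile
#' @param object a `base_bias`
#' @param ... ignored
#' @return a ggplot
#' @method autoplot base_bias
#' @export
autoplot.base_bias <- function(object, ...) {
  dat <- as_tibble(object) |>
    mutate(base = ifelse(.data$base == "T", "U", .data$base))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$position), y = .data$freq,
                                    fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "position from 5' end", y = "frequency", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Normalise a read-length histogram to a fixed library size
#'
#' Rescales each length bin by `scale_to / total`, the convention used to
#' compare length distributions across libraries of different depth
#' (default: counts per 10^7 mapped piRNAs).
#'
#' @param hist tibble with columns `length` and `count`
#' @param total total mapped piRNA count (> 0); defaults to `sum(hist$count)`
#' @param scale_to target library size (default 1e7)
#' @return tibble with `length` and normalised `count`
#' @export
normalize_counts <- function(hist, total = sum(hist$count), scale_to = 1e7) {
  if (total <= 0) abort("`total` must be > 0")
  mutate(as_tibble(hist), count = .data$count * scale_to / total)
}

#' Weighted read-length histogram of an alignment set
#' @param alignments weighted alignment tibble
#' @return tibble: length, count (summed weights)
#' @export
length_histogram <- function(alignments) {
  alignments |>
    group_by(.data$length) |>
    summarise(count = sum(.data$weight), .groups = "drop") |>
    arrange(.data$length)
}
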