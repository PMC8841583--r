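#' Kimura two-parameter distance
#'
#' `K = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))` where `P` is the transition
#' proportion and `Q` the transversion proportion among compared sites.
#' Defined only while `1 - 2P - Q > 0` and `1 - 2Q > 0`; outside that domain
#' the distance is saturated and an error is raised.
#'
#' @param P,Q transition and transversion proportions (vectorised)
#' @return K2P distance in substitutions per site
#' @export
#' @examples
#' kimura2p(0, 0)          # 0
#' kimura2p(0.1, 0.05)     # ~0.1702
kimura2p <- function(P, Q) {
  if (any(P < 0 | Q < 0 | P + Q > 1)) abort("need P, Q >= 0 and P + Q <= 1")
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  if (any(a <= 0 | b <= 0))
    abort("K2P distance undefined: sequences saturated (1-2P-Q or 1-2Q <= 0)")
  -0.5 * log(a * sqrt(b))
}

#' Estimate divergence of a repeat copy from its family consensus
#'
#' Counts transitions and transversions over aligned, unambiguous sites of two
#' equal-length sequences (the synthetic generator produces gap-free copies in
#' consensus coordinates) and converts to a K2P distance.
#'
#' @param copy,consensus equal-length DNA strings; sites with N in either are
#'   excluded
#' @return one-row tibble: `P`, `Q`, `K`, `sites`
#' @export
copy_divergence <- function(copy, consensus) {
  a <- seq_chars(toupper(chartr("U", "T", copy)))
  b <- seq_chars(toupper(chartr("U", "T", consensus)))
  if (length(a) != length(b))
    abort("`copy` and `consensus` must have equal length (no-indel comparison)")
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) abort("no comparable sites")
  diff <- a != b
  is_ts <- diff & (TRANSITION_OF[b] == a)
  P <- sum(is_ts) / n
  Q <- sum(diff & !is_ts) / n
  tibble(P = P, Q = Q, K = kimura2p(P, Q), sites = n)
}

#' Molecular-clock parameters for the landscape age axis
#'
#' The clock maps 0.01 substitutions/site to `mya_per_001` million years.  The
#' default 3.4 anchors the substitution ratios 0.05 and 0.10 to 17 and 34 Mya,
#' the hybridisation and speciation times of the L/S subgenome ancestors; the
#' literature range for this clock in *Xenopus* is 3.23-3.33 and can be set
#' instead.
#'
#' @param mya_per_001 million years per 0.01 substitutions/site (> 0)
#' @return a `clock_params` list
#' @export
clock_params <- function(mya_per_001 = 3.4) {
  if (!is.numeric(mya_per_001) || mya_per_001 <= 0)
    abort("`mya_per_001` must be > 0")
  structure(list(mya_per_001 = mya_per_001), class = "clock_params")
}

#' Convert K2P distance to age in million years
#'
#' Linear and invertible: `age = (K / 0.01) * mya_per_001`.
#'
#' @param K K2P distance(s), substitutions/site, >= 0
#' @param clock a [clock_params()]
#' @return age(s) in Mya
#' @export
#' @examples
#' time_axis(c(0, 0.05, 0.10))  # 0, 17, 34 under the default clock
time_axis <- function(K, clock = clock_params()) {
  if (any(K < 0)) abort("`K` must be >= 0")
  (K / 0.01) * clock$mya_per_001
}

#' Build a transposable-element divergence landscape
#'
#' Each annotated copy contributes its base length to the 0.01-wide divergence
#' bin containing its K2P distance; bin masses are normalised by total genome
#' length, so the landscape reads as "fraction of the genome occupied by
#' copies of this age".  No smoothing: one copy, one bin.
#'
#' @param copies tibble with `start`, `end`, `divergence` and a grouping column
#'   (`class` or `superfamily`); rows with `NA` divergence are dropped with a
#'   warning
#' @param genome_length total genome size in bases
#' @param group_by `"class"` or `"superfamily"`
#' @param bin_width divergence bin width in substitutions/site
#' @param clock a [clock_params()] for the age axis
#' @return a `te_landscape` tibble: group, bin_low, bin_high, fraction, age_mya
#'   (age of the bin lower edge)
#' @export
build_landscape <- function(copies, genome_length,
                            group_by = c("class", "superfamily"),
                            bin_width = 0.01, clock = clock_params()) {
  group_by <- match.arg(group_by)
  if (nrow(copies) == 0L) {
    out <- tibble(group = character(), bin_low = numeric(), bin_high = numeric(),
                  fraction = numeric(), age_mya = numeric())
    return(structure(out, class = c("te_landscape", class(out))))
  }
  nmiss <- sum(is.na(copies$divergence))
  if (nmiss > 0) {
    warn(sprintf("%d copies without divergence dropped from the landscape", nmiss))
    copies <- filter(copies, !is.na(.data$divergence))
  }
  out <- copies |>
    mutate(group = .data[[group_by]],
           bin_low = floor(.data$divergence / bin_width) * bin_width,
           len = .data$end - .data$start) |>
    group_by(.data$group, .data$bin_low) |>
    summarise(fraction = sum(.data$len) / genome_length, .groups = "drop") |>
    mutate(bin_high = .data$bin_low + bin_width,
           age_mya = time_axis(.data$bin_low, clock)) |>
    select("group", "bin_low", "bin_high", "fraction", "age_mya") |>
    arrange(.data$group, .data$bin_low)
  structure(out, class = c("te_landscape", class(out)))
}

#' Modal divergence bin per landscape group
#' @param landscape a `te_landscape`
#' @return tibble: group, bin_low, bin_high, fraction of the heaviest bin
#' @export
modal_bin <- function(landscape) {
  landscape |>
    as_tibble() |>
    group_by(.data$group) |>
    filter(.data$fraction == max(.data$fraction)) |>
    arrange(.data$bin_low) |>
    dplyr::slice(1) |>
    ungroup()
}

#' @method glance te_landscape
#' @export
glance.te_landscape <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$group) |>
    summarise(genome_fraction = sum(.data$fraction),
              modal_bin_low = .data$bin_low[which.max(.data$fraction)],
              n_bins = dplyr::n(), .groups = "drop")
}

#' @method tidy te_landscape
#' @export
tidy.te_landscape <- function(x, ...) as_tibble(x)

#' Plot a TE divergence landscape
#'
#' Stacked-bar landscape of genome fraction by divergence bin, coloured by
#' group, with a secondary molecular-clock age axis.
#'
#' @param object a `te_landscape`
#' @param clock a [clock_params()] used for the secondary axis
#' @param ... ignored
#' @return a ggplot
#' @method autoplot te_landscape
#' @export
autoplot.te_landscape <- function(object, clock = clock_params(), ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$bin_low, y = 100 * .data$fraction,
                               fill = .data$group)) +
    ggplot2::geom_col(width = min(object$bin_high - object$bin_low), position = "stack") +
    ggplot2::scale_x_continuous(
      name = "substitution ratio (K2P, subst/site)",
      sec.axis = ggplot2::sec_axis(~ time_axis(.x, clock), name = "age (Mya)")) +
    ggplot2::labs(y = "% of genome", fill = NULL) +
    ggplot2::theme_minimal()
}
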