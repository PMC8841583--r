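CATEGORY_LEVELS <- c("dna_transposon", "retrotransposon", "satellite",
                     "simple_repeat", "unknown_repeat", "exon", "intron", "other")

REPEAT_CATEGORY <- c(DNA = "dna_transposon", LINE = "retrotransposon",
                     SINE = "retrotransposon", LTR = "retrotransposon",
                     satellite = "satellite", simple = "simple_repeat",
                     unknown = "unknown_repeat")

#' Mean pairwise K2P diversity of a repeat family
#'
#' Computes the mean pairwise Kimura two-parameter distance among a family's
#' copies, compared in the shared consensus coordinate frame (all copies
#' gap-free and equal-length in synthetic mode).  Used to prioritise repeat
#' annotations where they overlap: younger (lower-diversity) families win.
#'
#' @param copies character vector of copy sequences (consensus coordinates)
#' @return diversity in substitutions/site; a single copy yields 0 with a
#'   warning flag
#' @export
family_diversity <- function(copies) {
  n <- length(copies)
  if (n == 0L) abort("no copies supplied")
  if (n == 1L) {
    warn("single-copy family: diversity set to 0")
    return(0)
  }
  tot <- 0; m <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + copy_divergence(copies[i], copies[j])$K
    m <- m + 1L
  }
  tot / m
}

#' Resolve overlapping repeat annotations by family diversity
#'
#' Wherever two repeat annotations overlap, the contested bases go to the
#' annotation whose family diversity is lower; ties are broken by earlier
#' start, then lexicographic family name.  Output intervals are disjoint.
#'
#' @param annotations tibble: chrom, start, end, family, class, superfamily,
#'   and optional divergence
#' @param diversities named numeric vector: family -> diversity score
#' @return annotation tibble with disjoint intervals (rows may be split)
#' @export
resolve_repeat_overlaps <- function(annotations, diversities) {
  if (nrow(annotations) == 0L) return(as_tibble(annotations))
  missing_fams <- setdiff(unique(annotations$family), names(diversities))
  if (length(missing_fams) > 0L)
    abort(paste("no diversity score for families:",
                paste(missing_fams, collapse = ", ")))
  ann <- annotations |>
    mutate(.div = unname(diversities[.data$family])) |>
    arrange(.data$.div, .data$start, .data$family)
  out <- list()
  for (ch in unique(ann$chrom)) {
    a <- filter(ann, .data$chrom == !!ch)
    claimed <- IRanges::IRanges()
    for (i in seq_len(nrow(a))) {
      iv <- IRanges::IRanges(start = a$start[i] + 1L, end = a$end[i])
      free <- IRanges::setdiff(iv, claimed)
      claimed <- IRanges::union(claimed, iv)
      if (length(free) == 0L) next
      out[[length(out) + 1L]] <- tibble(
        chrom = ch, start = IRanges::start(free) - 1L, end = IRanges::end(free),
        family = a$family[i], class = a$class[i], superfamily = a$superfamily[i],
        divergence = if ("divergence" %in% names(a)) a$divergence[i] else NA_real_)
    }
  }
  bind_rows(out) |> arrange(.data$chrom, .data$start)
}

#' Classify every genome base into eight categories
#'
#' Priority per base: repeat categories first (DNA transposon,
#' retrotransposon, satellite, simple repeat, unknown repeat — the repeat
#' annotations must already be disjoint), then exon, then intron (gene minus
#' exon), then `other`.  A transposon thus hides any exon it overlaps, and an
#' exon hides the surrounding intron.
#'
#' @param repeats disjoint repeat annotation tibble (chrom, start, end, class)
#' @param genes gene annotation tibble (chrom, start, end, gene_id, feature
#'   with "gene" and "exon" rows; exons must lie within their gene)
#' @param genome_lengths named integer vector of chromosome lengths
#' @return a `category_map` tibble: chrom, start, end, category — a disjoint
#'   partition of every chromosome
#' @export
classify_genome <- function(repeats, genes, genome_lengths) {
  gene_iv <- filter(genes, .data$feature == "gene")
  exon_iv <- filter(genes, .data$feature == "exon")
  # validate exons sit inside genes
  if (nrow(exon_iv) > 0L) for (i in seq_len(nrow(exon_iv))) {
    g <- gene_iv[gene_iv$gene_id == exon_iv$gene_id[i] &
                 gene_iv$chrom == exon_iv$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L || exon_iv$start[i] < g$start[1] || exon_iv$end[i] > g$end[1])
      abort(sprintf("exon of %s outside its gene", exon_iv$gene_id[i]))
  }
  out <- list()
  for (ch in names(genome_lengths)) {
    G <- genome_lengths[[ch]]
    rep_ch <- filter(repeats, .data$chrom == !!ch)
    taken <- IRanges::IRanges()
    add <- function(iv, category) {
      if (length(iv) == 0L) return(invisible(NULL))
      out[[length(out) + 1L]] <<- tibble(
        chrom = ch, start = IRanges::start(iv) - 1L, end = IRanges::end(iv),
        category = category)
      taken <<- IRanges::reduce(IRanges::union(taken, iv))
      invisible(NULL)
    }
    if (nrow(rep_ch) > 0L) {
      rep_ch <- mutate(rep_ch, category = unname(REPEAT_CATEGORY[.data$class]))
      if (any(is.na(rep_ch$category)))
        abort("unknown repeat class in annotation")
      for (cat in unique(rep_ch$category)) {
        r <- filter(rep_ch, .data$category == !!cat)
        add(IRanges::reduce(IRanges::IRanges(r$start + 1L, r$end)), cat)
      }
    }
    ex <- filter(exon_iv, .data$chrom == !!ch)
    if (nrow(ex) > 0L) {
      iv <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
      add(IRanges::setdiff(iv, taken), "exon")
    }
    gn <- filter(gene_iv, .data$chrom == !!ch)
    if (nrow(gn) > 0L) {
      iv <- IRanges::reduce(IRanges::IRanges(gn$start + 1L, gn$end))
      add(IRanges::setdiff(iv, taken), "intron")
    }
    add(IRanges::setdiff(IRanges::IRanges(1L, G), taken), "other")
  }
  res <- bind_rows(out) |>
    mutate(category = factor(.data$category, levels = CATEGORY_LEVELS)) |>
    arrange(.data$chrom, .data$start)
  structure(res, class = c("category_map", class(res)))
}

#' Category fractions of a genome, interval set, or weighted piRNA set
#'
#' With `alignments`, attributes each alignment's weight to the category of
#' its 5' base and reports weight fractions ("% of total piRNAs").  With
#' `intervals`, reports base fractions of the given intervals (e.g. a piRNA
#' cluster set).  With neither, reports base fractions of the whole genome.
#' Fractions always sum to 1.
#'
#' @param category_map a `category_map` from [classify_genome()]
#' @param alignments optional weighted alignment tibble
#' @param intervals optional interval tibble (chrom, start, end)
#' @return tibble: category, fraction (all 8 categories, zeros kept)
#' @export
fraction_table <- function(category_map, alignments = NULL, intervals = NULL) {
  cm <- as_tibble(category_map)
  if (!is.null(alignments) && !is.null(intervals))
    abort("supply at most one of `alignments` and `intervals`")
  if (is.null(alignments) && is.null(intervals)) {
    agg <- cm |>
      group_by(.data$category) |>
      summarise(mass = sum(.data$end - .data$start), .groups = "drop")
  } else if (!is.null(intervals)) {
    mass <- setNames(numeric(length(CATEGORY_LEVELS)), CATEGORY_LEVELS)
    for (i in seq_len(nrow(intervals))) {
      seg <- cm[cm$chrom == intervals$chrom[i], , drop = FALSE]
      ov <- overlap_len(intervals$start[i], intervals$end[i], seg$start, seg$end)
      for (k in which(ov > 0))
        mass[as.character(seg$category[k])] <- mass[as.character(seg$category[k])] + ov[k]
    }
    agg <- tibble(category = names(mass), mass = unname(mass))
  } else {
    fp <- five_prime_pos(alignments$start, alignments$strand, alignments$length)
    mass <- setNames(numeric(length(CATEGORY_LEVELS)), CATEGORY_LEVELS)
    for (ch in unique(alignments$chrom)) {
      idx <- which(alignments$chrom == ch)
      seg <- cm[cm$chrom == ch, , drop = FALSE]
      pos <- findInterval(fp[idx], seg$start)  # segments sorted, partition
      cat_i <- as.character(seg$category[pos])
      w <- alignments$weight[idx]
      for (cc in unique(cat_i)) mass[cc] <- mass[cc] + sum(w[cat_i == cc])
    }
    agg <- tibble(category = names(mass), mass = unname(mass))
  }
  tibble(category = CATEGORY_LEVELS) |>
    left_join(mutate(agg, category = as.character(.data$category)), by = "category") |>
    mutate(mass = ifelse(is.na(.data$mass), 0, .data$mass),
           fraction = .data$mass / sum(.data$mass)) |>
    select("category", "fraction")
}

#' @method glance category_map
#' @export
glance.category_map <- function(x, ...) {
  fraction_table(x) |>
    tidyr::pivot_wider(names_from = "category", values_from = "fraction")
}

#' @method tidy category_map
#' @export
tidy.category_map <- function(x, ...) as_tibble(x)

#' Plot genome composition fractions
#' @param object a `category_map`
#' @param ... ignored
#' @return a ggplot
#' @method autoplot category_map
#' @export
autoplot.category_map <- function(object, ...) {
  ft <- fraction_table(object)
  ggplot2::ggplot(ft, ggplot2::aes(x = .data$category, y = 100 * .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of genome") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
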