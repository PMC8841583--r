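#' Describe a transposable-element family for simulation
#'
#' @param name family name, e.g. `"hAT-1"`
#' @param class repeat class, one of `"DNA"`, `"LINE"`, `"SINE"`, `"LTR"`
#' @param superfamily superfamily label, e.g. `"hAT"`, `"Kolobok"`, `"Mariner"`
#' @param consensus_length consensus length in bases
#' @param copy_number number of genomic copies to plant
#' @param target_divergence expected Kimura two-parameter distance of each copy
#'   to the consensus, in substitutions per site
#' @param tstv_ratio transition:transversion odds kappa (a substituted site is a
#'   transition with probability kappa / (kappa + 1))
#' @return a `te_family` list, consumed by [sim_config()]
#' @export
te_family <- function(name, class = c("DNA", "LINE", "SINE", "LTR"),
                      superfamily = name, consensus_length = 2000L,
                      copy_number = 10L, target_divergence = 0.05,
                      tstv_ratio = 2) {
  class <- match.arg(class)
  if (target_divergence < 0) abort("`target_divergence` must be >= 0")
  if (tstv_ratio <= 0) abort("`tstv_ratio` must be > 0")
  structure(list(name = name, class = class, superfamily = superfamily,
                 consensus_length = as.integer(consensus_length),
                 copy_number = as.integer(copy_number),
                 target_divergence = target_divergence,
                 tstv_ratio = tstv_ratio), class = "te_family")
}

#' Describe a gene model for simulation
#' @param n_exons,exon_length,intron_length exon count and per-feature lengths (bases)
#' @return a `gene_model` list, consumed by [sim_config()]
#' @export
gene_model <- function(n_exons = 4L, exon_length = 200L, intron_length = 800L) {
  structure(list(n_exons = as.integer(n_exons),
                 exon_length = as.integer(exon_length),
                 intron_length = as.integer(intron_length)), class = "gene_model")
}

#' Describe a piRNA cluster to plant
#'
#' @param length cluster span in bases (must exceed twice the maximum read length)
#' @param n_read_loci number of distinct primary read 5' positions
#' @param pingpong_fraction fraction of emitted reads that are opposite-strand
#'   ping-pong partners with an exact 10-nt 5' overlap
#' @param u1_fraction probability that a primary read's first base is U
#' @param a10_fraction probability that position 10 of a primary read is A (for
#'   an exact-overlap partner this same genomic base is its first base, so the
#'   partner's 1U rate equals `a10_fraction` and its 10A rate equals
#'   `u1_fraction`; set the two equal for uniform biases)
#' @param depth number of read instances emitted from the cluster
#' @param strand strand of primary reads, `"+"`, `"-"` or `"random"`
#' @param antisense_fraction fraction of non-partner reads emitted from
#'   independent loci on the opposite strand (clusters produce reads from both
#'   strands; these create the random-overlap background against which the
#'   10-nt ping-pong excess is measured)
#' @return a `cluster_spec` list, consumed by [sim_config()]
#' @export
cluster_spec <- function(length = 4000L, n_read_loci = 50L,
                         pingpong_fraction = 0.8, u1_fraction = 0.8,
                         a10_fraction = 0.8, depth = 10000L,
                         strand = "random", antisense_fraction = 0.3) {
  stopifnot_scalar_prob(pingpong_fraction, "pingpong_fraction")
  stopifnot_scalar_prob(u1_fraction, "u1_fraction")
  stopifnot_scalar_prob(a10_fraction, "a10_fraction")
  stopifnot_scalar_prob(antisense_fraction, "antisense_fraction")
  structure(list(length = as.integer(length), n_read_loci = as.integer(n_read_loci),
                 pingpong_fraction = pingpong_fraction, u1_fraction = u1_fraction,
                 a10_fraction = a10_fraction, depth = as.integer(depth),
                 strand = strand, antisense_fraction = antisense_fraction),
            class = "cluster_spec")
}

#' Simulation configuration for the synthetic genome generator
#'
#' Bundles everything [simulate_genome()] and [simulate_pirna_reads()] need:
#' genome size, TE families with target K2P divergences, gene models, piRNA
#' clusters with ping-pong and 1U/10A parameters, tandem repeats, and
#' multimapping copies.  The defaults emulate the regimes the downstream
#' statistics are designed for: strong ping-pong (0.8), strong 1U/10A biases
#' (0.8), deep sequencing (10^4 reads per cluster), and TE families planted at
#' young/intermediate/old divergences.
#'
#' @param genome_length genome size in bases (single chromosome `"chr1"`)
#' @param rng_seed integer seed; all outputs are deterministic given it
#' @param te_families list of [te_family()] entries
#' @param genes list of [gene_model()] entries
#' @param clusters list of [cluster_spec()] entries
#' @param satellites,simple_repeats lists of `list(unit_length=, n_units=, copies=)`
#'   tandem-repeat specs
#' @param multimap_copies extra genomic copies of the first cluster's sequence,
#'   creating multimapping reads
#' @param read_length_range inclusive read-length range in nt
#' @return a `sim_config` list
#' @export
sim_config <- function(genome_length = 100000L, rng_seed = 1L,
                       te_families = list(
                         te_family("hAT-1", "DNA", "hAT", 2000L, 12L, 0.05),
                         te_family("Kolobok-1", "DNA", "Kolobok", 1500L, 8L, 0.14),
                         te_family("L1-1", "LINE", "L1", 3000L, 6L, 0.10)
                       ),
                       genes = list(gene_model(), gene_model(3L, 150L, 600L)),
                       clusters = list(cluster_spec(), cluster_spec(length = 3000L)),
                       satellites = list(),
                       simple_repeats = list(),
                       multimap_copies = 0L,
                       read_length_range = c(24L, 32L)) {
  cfg <- structure(list(genome_length = as.integer(genome_length),
                        rng_seed = as.integer(rng_seed),
                        te_families = te_families, genes = genes,
                        clusters = clusters, satellites = satellites,
                        simple_repeats = simple_repeats,
                        multimap_copies = as.integer(multimap_copies),
                        read_length_range = as.integer(read_length_range)),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$genome_length < 1000L) abort("`genome_length` must be >= 1000")
  if (length(cfg$read_length_range) != 2L ||
      cfg$read_length_range[1] > cfg$read_length_range[2])
    abort("`read_length_range` must be c(min, max) with min <= max")
  max_len <- cfg$read_length_range[2]
  for (cl in cfg$clusters) {
    if (cl$length < 2L * max_len)
      abort("cluster shorter than twice the maximum read length cannot host reads")
  }
  planted <- sum(vapply(cfg$te_families, function(f) f$consensus_length * f$copy_number, numeric(1))) +
    sum(vapply(cfg$genes, function(g) g$n_exons * g$exon_length + (g$n_exons - 1L) * g$intron_length, numeric(1))) +
    sum(vapply(cfg$clusters, function(cl) cl$length, numeric(1))) * (1 + (cfg$multimap_copies > 0)) +
    sum(vapply(cfg$satellites, function(s) s$unit_length * s$n_units * s$copies, numeric(1))) +
    sum(vapply(cfg$simple_repeats, function(s) s$unit_length * s$n_units * s$copies, numeric(1)))
  if (planted > 0.9 * cfg$genome_length)
    abort("planted features exceed genome capacity (must fit in 90% of the genome)")
  invisible(cfg)
}

#' Mutate a consensus sequence under a Kimura two-parameter process
#'
#' Substitutions are placed at uniformly random sites with
#' transition:transversion odds `kappa`:1.  Placement is stratified: the
#' transition and transversion counts are fixed at the integers that bring the
#' realised K2P distance of the copy to the smallest achievable value at or
#' above `d` (site positions and transversion directions stay random), so
#' every copy's divergence equals the target up to integer-count rounding and
#' planted ages are exactly recoverable from the sequence.  No indels; length
#' is preserved.
#'
#' @param consensus DNA string
#' @param d target K2P distance in substitutions/site (>= 0)
#' @param kappa transition:transversion odds (> 0)
#' @return mutated DNA string of the same length
#' @export
#' @examples
#' set.seed(1)
#' x <- paste(sample(c("A","C","G","T"), 100, TRUE), collapse = "")
#' mutate_copy(x, 0)      # identical
#' mutate_copy(x, 0.05)   # 5% K2P-diverged copy
mutate_copy <- function(consensus, d, kappa = 2) {
  if (d < 0) abort("`d` must be >= 0")
  if (kappa <= 0) abort("`kappa` must be > 0")
  if (d == 0) return(consensus)
  ch <- seq_chars(toupper(consensus))
  n <- length(ch)
  s <- k2p_site_rate(d, kappa)
  cnt <- k2p_counts(n, s, kappa, d)
  n_sub <- cnt[1] + cnt[2]
  if (n_sub == 0L) return(consensus)
  if (n_sub > n) abort("target divergence needs more substituted sites than available")
  hit <- sample.int(n, n_sub)
  ts_idx <- hit[seq_len(cnt[1])]
  tv_idx <- hit[-seq_len(cnt[1])]
  if (length(ts_idx)) ch[ts_idx] <- TRANSITION_OF[ch[ts_idx]]
  if (length(tv_idx)) {
    ch[tv_idx] <- vapply(ch[tv_idx], function(b) {
      tv <- setdiff(DNA_BASES, c(b, TRANSITION_OF[[b]]))
      tv[sample.int(2L, 1L)]
    }, character(1))
  }
  paste(ch, collapse = "")
}

# integer (transition, transversion) counts whose realised K2P distance is the
# smallest achievable value >= d (falling back to the closest below)
k2p_counts <- function(n, s, kappa, d) {
  ts0 <- n * s * kappa / (kappa + 1)
  tv0 <- n * s / (kappa + 1)
  cand <- expand.grid(ts = unique(c(floor(ts0), ceiling(ts0))),
                      tv = unique(c(floor(tv0), ceiling(tv0))))
  cand$K <- vapply(seq_len(nrow(cand)), function(i) {
    tryCatch(kimura2p(cand$ts[i] / n, cand$tv[i] / n), error = function(e) NA_real_)
  }, numeric(1))
  cand <- cand[!is.na(cand$K), , drop = FALSE]
  above <- cand[cand$K >= d, , drop = FALSE]
  pickfrom <- if (nrow(above) > 0L) above[which.min(above$K), ] else
    cand[which.max(cand$K), ]
  c(as.integer(pickfrom$ts), as.integer(pickfrom$tv))
}

# per-site substitution probability s so that K2P(P = s*k/(k+1), Q = s/(k+1)) = d
k2p_site_rate <- function(d, kappa) {
  f <- function(s) {
    P <- s * kappa / (kappa + 1)
    Q <- s / (kappa + 1)
    -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q)) - d
  }
  upper <- (kappa + 1) / (2 * kappa + 1) - 1e-9
  if (f(upper) < 0)
    abort("target divergence saturates the K2P process for this kappa")
  uniroot(f, c(1e-12, upper), tol = 1e-12)$root
}

# ---- feature placement -------------------------------------------------------

# plan non-overlapping intervals for all features at once: features are put in
# random genomic order, each preceded by at least its margin, with the leftover
# space distributed randomly between them.  Succeeds whenever the features fit
# at their minimum spacing, regardless of occupancy.
plan_layout <- function(lengths, margins, genome_length) {
  n <- length(lengths)
  if (n == 0L) return(matrix(integer(0), ncol = 2))
  ord <- sample.int(n)
  need <- sum(lengths) + sum(margins)
  if (need > genome_length)
    abort("planted features exceed genome capacity: no free interval large enough")
  w <- stats::rexp(n + 1L)
  slack <- floor((genome_length - need) * w / sum(w))
  starts <- integer(n)
  p <- 0L
  for (j in seq_len(n)) {
    i <- ord[j]
    p <- p + margins[i] + slack[j]
    starts[i] <- p
    p <- p + lengths[i]
  }
  matrix(c(starts, starts + lengths), ncol = 2)
}

#' Simulate a toy genome with planted TEs, genes, tandem repeats, and piRNA clusters
#'
#' Builds a random background sequence, then plants (without overlaps) mutated
#' copies of each TE family consensus, gene models with exon/intron structure,
#' tandem repeats, and piRNA clusters whose read 5'-end bases realise the
#' requested 1U/10A rates.  When `multimap_copies > 0` the first cluster's
#' final sequence is duplicated at that many extra loci so that its reads
#' multimap.  Deterministic given `config$rng_seed`.
#'
#' All intervals are 0-based half-open.
#'
#' @param config a [sim_config()]
#' @return a `sim_genome` list with elements
#'   \describe{
#'     \item{genome}{named character vector of chromosome sequences}
#'     \item{repeats}{tibble: chrom, start, end, family, class, superfamily,
#'       divergence (realised K2P to consensus)}
#'     \item{genes}{tibble: chrom, start, end, strand, gene_id, feature
#'       (gene/exon rows)}
#'     \item{truth}{list: clusters, loci, te_consensus, multimap_loci}
#'     \item{config}{the input config}
#'   }
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  with_seed(config$rng_seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(config) {
  G <- config$genome_length
  ch <- sample(DNA_BASES, G, replace = TRUE)

  # plan all feature intervals up front, in the same order they are planted
  # below; clusters (and multimap copies of them) get a wide margin so that
  # distinct read-producing loci never abut
  lens <- integer(0); margs <- integer(0)
  addf <- function(len, margin) {
    lens[length(lens) + 1L] <<- as.integer(len)
    margs[length(margs) + 1L] <<- as.integer(margin)
  }
  for (fam in config$te_families)
    for (i in seq_len(fam$copy_number)) addf(fam$consensus_length, 10L)
  for (s in config$satellites)
    for (i in seq_len(s$copies %||% 1L)) addf(s$unit_length * s$n_units, 10L)
  for (s in config$simple_repeats)
    for (i in seq_len(s$copies %||% 1L)) addf(s$unit_length * s$n_units, 10L)
  for (g in config$genes)
    addf(g$n_exons * g$exon_length + (g$n_exons - 1L) * g$intron_length, 10L)
  for (cl in config$clusters) addf(cl$length, 6000L)
  if (config$multimap_copies > 0L && length(config$clusters) > 0L)
    for (i in seq_len(config$multimap_copies))
      addf(config$clusters[[1]]$length, 6000L)
  plan <- plan_layout(lens, margs, G)
  iv_idx <- 0L
  take_iv <- function() {
    iv_idx <<- iv_idx + 1L
    plan[iv_idx, ]
  }

  rep_rows <- list()
  te_consensus <- list()
  for (fam in config$te_families) {
    cons <- rand_dna(fam$consensus_length)
    te_consensus[[fam$name]] <- cons
    if (fam$copy_number > 0) for (i in seq_len(fam$copy_number)) {
      copy <- mutate_copy(cons, fam$target_divergence, fam$tstv_ratio)
      iv <- take_iv()
      ch[(iv[1] + 1L):iv[2]] <- seq_chars(copy)
      div <- copy_divergence(copy, cons)
      rep_rows[[length(rep_rows) + 1L]] <- tibble(
        chrom = "chr1", start = iv[1], end = iv[2], family = fam$name,
        class = fam$class, superfamily = fam$superfamily, divergence = div$K)
    }
  }

  for (spec in seq_along(config$satellites)) {
    s <- config$satellites[[spec]]
    unit <- rand_dna(s$unit_length)
    for (i in seq_len(s$copies %||% 1L)) {
      block <- strrep(unit, s$n_units)
      iv <- take_iv()
      ch[(iv[1] + 1L):iv[2]] <- seq_chars(block)
      rep_rows[[length(rep_rows) + 1L]] <- tibble(
        chrom = "chr1", start = iv[1], end = iv[2],
        family = paste0("SAT-", spec), class = "satellite",
        superfamily = "satellite", divergence = NA_real_)
    }
  }
  for (spec in seq_along(config$simple_repeats)) {
    s <- config$simple_repeats[[spec]]
    unit <- rand_dna(s$unit_length)
    for (i in seq_len(s$copies %||% 1L)) {
      block <- strrep(unit, s$n_units)
      iv <- take_iv()
      ch[(iv[1] + 1L):iv[2]] <- seq_chars(block)
      rep_rows[[length(rep_rows) + 1L]] <- tibble(
        chrom = "chr1", start = iv[1], end = iv[2],
        family = paste0("SSR-", spec), class = "simple",
        superfamily = "simple", divergence = NA_real_)
    }
  }
  repeats <- if (length(rep_rows)) bind_rows(rep_rows) else
    tibble(chrom = character(), start = integer(), end = integer(),
           family = character(), class = character(), superfamily = character(),
           divergence = numeric())

  gene_rows <- list()
  for (gi in seq_along(config$genes)) {
    g <- config$genes[[gi]]
    span <- g$n_exons * g$exon_length + (g$n_exons - 1L) * g$intron_length
    iv <- take_iv()
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("gene%02d", gi)
    gene_rows[[length(gene_rows) + 1L]] <- tibble(
      chrom = "chr1", start = iv[1], end = iv[2], strand = strand,
      gene_id = gid, feature = "gene")
    for (e in seq_len(g$n_exons)) {
      es <- iv[1] + (e - 1L) * (g$exon_length + g$intron_length)
      gene_rows[[length(gene_rows) + 1L]] <- tibble(
        chrom = "chr1", start = es, end = es + g$exon_length, strand = strand,
        gene_id = gid, feature = "exon")
    }
  }
  genes <- if (length(gene_rows)) bind_rows(gene_rows) else
    tibble(chrom = character(), start = integer(), end = integer(),
           strand = character(), gene_id = character(), feature = character())

  # piRNA clusters: plant the interval, pick read loci, and fix 5'/10 bases
  max_len <- config$read_length_range[2]
  cl_rows <- list()
  locus_rows <- list()
  for (ci in seq_along(config$clusters)) {
    cl <- config$clusters[[ci]]
    # piRNA clusters are discrete, well-separated loci; the wide margin keeps
    # distinct planted clusters from abutting into one read-density run
    iv <- take_iv()
    strand <- if (identical(cl$strand, "random")) sample(c("+", "-"), 1L) else cl$strand
    cid <- sprintf("cluster%02d", ci)
    cl_rows[[length(cl_rows) + 1L]] <- tibble(
      chrom = "chr1", start = iv[1], end = iv[2], strand = strand,
      cluster_id = cid, pingpong_fraction = cl$pingpong_fraction,
      u1_fraction = cl$u1_fraction, a10_fraction = cl$a10_fraction,
      antisense_fraction = cl$antisense_fraction,
      n_read_loci = cl$n_read_loci, depth = cl$depth)
    sgn <- if (strand == "+") 1L else -1L
    # primary 5' position g must leave room for the read and its partner
    if (strand == "+") {
      lo <- iv[1] + max_len - 10L
      hi <- iv[2] - max_len
    } else {
      lo <- iv[1] + max_len - 1L
      hi <- iv[2] - max_len + 9L
    }
    loci <- sort(sample(lo:hi, min(cl$n_read_loci, hi - lo + 1L)))
    # two independent primary 5' ends exactly 10 nt apart in the pair register
    # would collide with partner 5' bases; keep the registers clean
    while (any(drop <- loci %in% (loci + sgn * 9L)))
      loci <- loci[!drop]
    # opposite-strand background loci at a few fixed 5'-5' registers relative
    # to primary loci (excluding the ping-pong register d = 10), giving the
    # structured off-10 overlap background real libraries show
    anti_strand <- if (strand == "+") "-" else "+"
    if (cl$antisense_fraction > 0) {
      offsets <- sample(setdiff(1:20, 9L), 3L)
      src <- sample(loci, min(length(loci), max(5L, ceiling(length(loci) / 2))))
      anti <- sort(unique(src + sgn * sample(offsets, length(src), TRUE)))
      # keep the d = 10 register free of background and avoid both-strand loci
      # sharing one 5' base
      anti <- setdiff(anti, c(loci, loci + sgn * 9L))
    } else anti <- integer(0)
    # 5' base: U on the read's strand at rate u1; read position 10: A at rate
    # a10.  5'-end bases take precedence: a position-10 edit never overwrites
    # a base that is some read's first base (for an exact ping-pong pair the
    # two roles coincide on the complementary strand and agree by design).
    five_idx <- c(loci, anti) + 1L
    set_bases <- function(positions, read_sgn, what) {
      base5 <- if (read_sgn > 0) "T" else "A"
      base10 <- if (read_sgn > 0) "A" else "T"
      for (g0 in positions) {
        if (what == "five") {
          p1 <- g0 + 1L               # 1-based index into ch
          ch[p1] <<- if (runif(1) < cl$u1_fraction) base5 else
            sample(setdiff(DNA_BASES, base5), 1L)
        } else {
          p10 <- g0 + read_sgn * 9L + 1L
          if (p10 %in% five_idx) next
          ch[p10] <<- if (runif(1) < cl$a10_fraction) base10 else
            sample(setdiff(DNA_BASES, base10), 1L)
        }
      }
    }
    set_bases(loci, sgn, "five")
    set_bases(anti, -sgn, "five")
    # primary position-10 edits last: they double as partner 5' bases, so they
    # outrank background reads' position-10 edits where targets collide
    set_bases(anti, -sgn, "ten")
    set_bases(loci, sgn, "ten")
    locus_rows[[length(locus_rows) + 1L]] <- bind_rows(
      tibble(cluster_id = cid, chrom = "chr1", five_prime = loci,
             strand = strand, role = "primary"),
      if (length(anti)) tibble(cluster_id = cid, chrom = "chr1",
                               five_prime = anti, strand = anti_strand,
                               role = "antisense"))
  }
  clusters <- if (length(cl_rows)) bind_rows(cl_rows) else
    tibble(chrom = character(), start = integer(), end = integer(),
           strand = character(), cluster_id = character())
  loci_tbl <- if (length(locus_rows)) bind_rows(locus_rows) else
    tibble(cluster_id = character(), chrom = character(),
           five_prime = integer(), strand = character(), role = character())

  multimap <- tibble(chrom = character(), start = integer(), end = integer(),
                     src_cluster = character())
  if (config$multimap_copies > 0L && nrow(clusters) > 0L) {
    src <- clusters[1, ]
    block <- paste(ch[(src$start + 1L):src$end], collapse = "")
    for (i in seq_len(config$multimap_copies)) {
      iv <- take_iv()
      ch[(iv[1] + 1L):iv[2]] <- seq_chars(block)
      multimap <- bind_rows(multimap, tibble(
        chrom = "chr1", start = iv[1], end = iv[2],
        src_cluster = src$cluster_id))
    }
  }

  structure(list(
    genome = c(chr1 = paste(ch, collapse = "")),
    repeats = repeats, genes = genes,
    truth = list(clusters = clusters, loci = loci_tbl,
                 te_consensus = te_consensus, multimap_loci = multimap),
    config = config), class = "sim_genome")
}

#' Simulate piRNA reads from planted clusters
#'
#' Emits `depth` read instances per cluster.  A `pingpong_fraction` of
#' instances are opposite-strand partners whose 5' ends overlap a primary
#' locus's 5' end by exactly 10 nt; the remainder are primary reads.  Read
#' lengths are uniform over `read_length_range`.  Identical sequences are
#' collapsed into one record with a count (the "id-count" FASTA dialect).
#'
#' @param sim a `sim_genome` from [simulate_genome()]
#' @param seed integer seed for read sampling (defaults to `rng_seed + 1`)
#' @return list with `reads` (tibble: id, seq, count) and `truth_reads`
#'   (instance-level tibble: cluster_id, five_prime, strand, length, is_partner)
#' @export
simulate_pirna_reads <- function(sim, seed = sim$config$rng_seed + 1L) {
  stopifnot(inherits(sim, "sim_genome"))
  if (nrow(sim$truth$clusters) == 0L) abort("no clusters planted in this genome")
  with_seed(seed, simulate_reads_impl(sim))
}

simulate_reads_impl <- function(sim) {
  cfg <- sim$config
  gch <- seq_chars(sim$genome[["chr1"]])
  lens <- cfg$read_length_range[1]:cfg$read_length_range[2]
  inst <- list()
  for (ci in seq_len(nrow(sim$truth$clusters))) {
    clt <- sim$truth$clusters[ci, ]
    loci <- filter(sim$truth$loci, .data$cluster_id == clt$cluster_id,
                   .data$role == "primary")
    anti_loci <- filter(sim$truth$loci, .data$cluster_id == clt$cluster_id,
                        .data$role == "antisense")
    n_pp <- round(clt$depth * clt$pingpong_fraction)
    n_anti <- if (nrow(anti_loci) > 0L)
      round((clt$depth - n_pp) * clt$antisense_fraction) else 0L
    n_pri <- clt$depth - n_pp - n_anti
    pick <- function(tbl, n) tbl$five_prime[sample.int(nrow(tbl), n, replace = TRUE)]
    sgn <- if (clt$strand == "+") 1L else -1L
    pri <- tibble(cluster_id = clt$cluster_id,
                  five_prime = pick(loci, n_pri), strand = clt$strand,
                  length = sample(lens, n_pri, replace = TRUE),
                  is_partner = FALSE)
    anti <- if (n_anti > 0L) tibble(
      cluster_id = clt$cluster_id,
      five_prime = pick(anti_loci, n_anti),
      strand = if (clt$strand == "+") "-" else "+",
      length = sample(lens, n_anti, replace = TRUE),
      is_partner = FALSE) else NULL
    par <- if (n_pp > 0L) tibble(
      cluster_id = clt$cluster_id,
      five_prime = pick(loci, n_pp) + sgn * 9L,
      strand = if (clt$strand == "+") "-" else "+",
      length = sample(lens, n_pp, replace = TRUE),
      is_partner = TRUE) else NULL
    inst[[ci]] <- bind_rows(pri, anti, par)
  }
  truth_reads <- bind_rows(inst)
  # extract sequences (read orientation)
  seqs <- vapply(seq_len(nrow(truth_reads)), function(i) {
    fp <- truth_reads$five_prime[i]; L <- truth_reads$length[i]
    if (truth_reads$strand[i] == "+") {
      paste(gch[(fp + 1L):(fp + L)], collapse = "")
    } else {
      revcomp(paste(gch[(fp - L + 2L):(fp + 1L)], collapse = ""))
    }
  }, character(1))
  truth_reads$seq <- seqs
  reads <- truth_reads |>
    count(.data$seq, name = "count") |>
    arrange(desc(.data$count), .data$seq) |>
    mutate(id = sprintf("r%06d", row_number())) |>
    select("id", "seq", "count")
  list(reads = reads, truth_reads = truth_reads)
}

#' Derive a second genome from a simulated one
#'
#' Produces a homologous genome for synteny and conservation experiments:
#' the whole sequence is passed through the K2P mutation process at divergence
#' `d`, and optionally the bodies of selected piRNA clusters are replaced by
#' unrelated random sequence ("cluster lost, flanks kept").  Annotations carry
#' over with unchanged coordinates (no indels are introduced).
#'
#' @param sim a `sim_genome`
#' @param d divergence applied to every base (substitutions/site)
#' @param kappa transition:transversion odds
#' @param drop_cluster_bodies character vector of cluster_ids whose planted
#'   interval is overwritten with random sequence
#' @param seed RNG seed
#' @return a `sim_genome` with mutated sequence and inherited annotations
#' @export
derive_genome <- function(sim, d = 0.05, kappa = 2,
                          drop_cluster_bodies = character(), seed = 99L) {
  stopifnot(inherits(sim, "sim_genome"))
  with_seed(seed, {
    seqs <- vapply(sim$genome, mutate_copy, character(1), d = d, kappa = kappa)
    names(seqs) <- names(sim$genome)
    for (cid in drop_cluster_bodies) {
      clt <- filter(sim$truth$clusters, .data$cluster_id == cid)
      if (nrow(clt) == 0L) abort(sprintf("unknown cluster_id '%s'", cid))
      ch <- seq_chars(seqs[[clt$chrom]])
      ch[(clt$start + 1L):clt$end] <- sample(DNA_BASES, clt$end - clt$start, replace = TRUE)
      seqs[[clt$chrom]] <- paste(ch, collapse = "")
    }
    out <- sim
    out$genome <- seqs
    out
  })
}
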