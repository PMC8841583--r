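#' Run the full piRNA/TE analysis pipeline on a synthetic genome
#'
#' Self-contained end-to-end run: simulates a genome and two gonadal small-RNA
#' libraries from one [sim_config()], then executes read filtering, alignment
#' with best-stratum selection and weight reallocation, ping-pong and 1U/10A
#' signatures, cluster calling by both detectors with merging and
#' cross-sample comparison, genome composition accounting, and the TE
#' divergence landscape.  Stage parameters default to the pipeline's canonical
#' settings (24-32 nt, 18-nt seed, 2 mismatches, 10-kb reallocation window,
#' 1 locus/kb and 10-locus cluster filters, assembly chaining 50/50 then
#' 500/250/50, 0.5 common-cluster fraction, 0.01 landscape bins).
#'
#' All stages are deterministic given `config$rng_seed`; re-running with the
#' same config reproduces every output bit-for-bit.  When `out_dir` is given,
#' standard-format outputs (FASTA, GFF3, BED6, TSV) and a JSON run manifest
#' (parameters, seed, input checksums) are written there.
#'
#' @param config a [sim_config()]
#' @param out_dir optional output directory (created if needed)
#' @param samples labels for the two simulated libraries (arbitrary condition
#'   names; defaults "ovary" and "testis")
#' @param ncrna_refs ncRNA reference sequences for read exclusion
#' @param min_len,max_len read length window (nt)
#' @param seed_len,max_mm,protect_3p,window alignment-rule and reallocation
#'   parameters, see [align_reads()]
#' @param cluster_window,min_density,min_loci density-detector parameters
#' @param min_frag,gap,min_merge_len,merge_gap,min_weight assembly-detector
#'   parameters
#' @param common_frac common-cluster overlap fraction
#' @param bin_width landscape bin width (substitutions/site)
#' @param clock a [clock_params()]
#' @return a `pirnascape_run` list: sim, reads, alignments, pingpong, bias,
#'   length_hist, clusters (per sample + comparison), composition, landscape,
#'   manifest
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         samples = c("ovary", "testis"),
                         ncrna_refs = character(),
                         min_len = 24L, max_len = 32L,
                         seed_len = 18L, max_mm = 2L, protect_3p = 2L,
                         window = 10000L,
                         cluster_window = 5000L, min_density = 1, min_loci = 10L,
                         min_frag = 50L, gap = 50L, min_merge_len = 500L,
                         merge_gap = 250L, min_weight = 50,
                         common_frac = 0.5, bin_width = 0.01,
                         clock = clock_params()) {
  stopifnot(length(samples) == 2L)
  sim <- simulate_genome(config)

  per_sample <- list()
  for (si in seq_along(samples)) {
    sm <- samples[si]
    rd <- simulate_pirna_reads(sim, seed = config$rng_seed + si)
    reads <- rd$reads |>
      exclude_annotated_rna(ncrna_refs) |>
      length_filter(min_len, max_len)
    aln <- align_reads(reads, sim$genome, seed_len, max_mm, protect_3p, window)
    pp <- pingpong_profile(aln)
    bias <- base_bias(aln, sim$genome)
    lh <- normalize_counts(length_histogram(aln))
    dens <- detect_density(aln, cluster_window, min_density, min_loci, sample = sm)
    asmb <- detect_assembly(aln, min_frag, gap, min_merge_len, merge_gap,
                            min_weight, sample = sm)
    per_sample[[sm]] <- list(reads = reads, alignments = aln, pingpong = pp,
                             bias = bias, length_hist = lh,
                             clusters = union_clusters(dens, asmb, aln))
  }
  comparison <- common_clusters(per_sample[[1]]$clusters,
                                per_sample[[2]]$clusters, common_frac)

  # composition: diversity-prioritised repeats, then the 8-way partition
  glen <- setNames(nchar(sim$genome), names(sim$genome))
  div <- family_diversities_from_genome(sim)
  resolved <- resolve_repeat_overlaps(sim$repeats, div)
  cmap <- classify_genome(resolved, sim$genes, glen)
  comp <- list(
    genome = fraction_table(cmap),
    pirna = lapply(per_sample, function(s) fraction_table(cmap, alignments = s$alignments)))

  te <- filter(sim$repeats, .data$class %in% c("DNA", "LINE", "SINE", "LTR"))
  landscape <- build_landscape(te, sum(glen), group_by = "class",
                               bin_width = bin_width, clock = clock)

  run <- structure(list(sim = sim, samples = per_sample,
                        comparison = comparison, category_map = cmap,
                        composition = comp, landscape = landscape),
                   class = "pirnascape_run")
  if (!is.null(out_dir)) run$manifest <- write_run_outputs(run, out_dir, config)
  run
}

# mean pairwise K2P per family, from planted copies in genome coordinates;
# families without class-level divergence (satellite/simple) get Inf so any
# transposon outranks them in overlap resolution
family_diversities_from_genome <- function(sim) {
  fams <- unique(sim$repeats$family)
  out <- setNames(rep(Inf, length(fams)), fams)
  for (fam in fams) {
    rr <- filter(sim$repeats, .data$family == !!fam, !is.na(.data$divergence))
    if (nrow(rr) == 0L) next
    copies <- substr(rep(sim$genome[rr$chrom], 1), rr$start + 1L, rr$end)
    out[fam] <- if (nrow(rr) >= 2L && length(unique(nchar(copies))) == 1L)
      family_diversity(copies) else 2 * mean(rr$divergence)
  }
  out
}

write_run_outputs <- function(run, out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_genome_fasta(run$sim$genome, p("genome.fa"))
  write_gff3(run$sim$genes, p("genes.gff3"))
  write_bed6(run$sim$repeats, p("repeats.bed"))
  write_tsv_file(run$sim$repeats, p("repeats.tsv"))
  for (sm in names(run$samples)) {
    s <- run$samples[[sm]]
    write_reads_fasta(s$reads, p(sprintf("%s.reads.fa", sm)))
    write_tsv_file(s$alignments, p(sprintf("%s.alignments.tsv", sm)))
    write_tsv_file(as_tibble(s$pingpong), p(sprintf("%s.pingpong.tsv", sm)))
    write_tsv_file(as_tibble(s$bias), p(sprintf("%s.base_bias.tsv", sm)))
    write_tsv_file(s$length_hist, p(sprintf("%s.length_hist.tsv", sm)))
    write_tsv_file(as_tibble(s$clusters), p(sprintf("%s.clusters.tsv", sm)))
    write_bed6(s$clusters, p(sprintf("%s.clusters.bed", sm)))
  }
  write_tsv_file(as_tibble(run$comparison$clusters), p("clusters.compared.tsv"))
  write_tsv_file(as_tibble(run$category_map), p("category_map.tsv"))
  write_tsv_file(run$composition$genome, p("composition.genome.tsv"))
  write_tsv_file(as_tibble(run$landscape), p("landscape.tsv"))
  manifest <- list(
    package = "pirnascape",
    version = as.character(utils::packageVersion("pirnascape")),
    rng_seed = config$rng_seed,
    genome_length = config$genome_length,
    parameters = list(read_length = c(24L, 32L), seed_len = 18L, max_mm = 2L,
                      reallocation_window = 10000L, min_density = 1,
                      min_loci = 10L, assembly = c(50L, 50L, 500L, 250L, 50L),
                      common_frac = 0.5, bin_width = 0.01),
    checksums = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest
}

#' @export
print.pirnascape_run <- function(x, ...) {
  cat("pirnascape pipeline run\n")
  cat(sprintf("  genome: %d bp, %d repeat copies, %d clusters planted\n",
              sum(nchar(x$sim$genome)), nrow(x$sim$repeats),
              nrow(x$sim$truth$clusters)))
  for (sm in names(x$samples)) {
    s <- x$samples[[sm]]
    g <- glance(s$pingpong)
    cat(sprintf("  %s: %d reads, %d alignments, z10 = %.2f, %d clusters\n",
                sm, nrow(s$reads), nrow(s$alignments), g$z10,
                nrow(s$clusters)))
  }
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
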