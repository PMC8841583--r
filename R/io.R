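#' Write a genome to FASTA
#' @param genome named character vector of chromosome sequences
#' @param path output file
#' @return `path`, invisibly
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(unlist(genome))
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file
#' @return named character vector of chromosome sequences
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write collapsed small-RNA reads as "id-count" FASTA
#'
#' Headers take the form `>id-count`, the collapsed-read dialect in which the
#' trailing integer is the read's copy number.
#'
#' @param reads tibble with `id`, `seq`, `count`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_reads_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- paste0(reads$id, "-", reads$count)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read small-RNA reads from FASTA or FASTQ
#'
#' Accepts the collapsed "id-count" FASTA dialect (count parsed from the
#' trailing `-<integer>` of the header); headers without it get count 1.
#' FASTQ files (by extension .fq/.fastq) are read with counts of 1.
#'
#' @param path input file
#' @return tibble: id, seq, count
#' @export
read_reads_fasta <- function(path) {
  if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
  } else {
    x <- Biostrings::readDNAStringSet(path)
  }
  hdr <- sub("\\s.*$", "", names(x))
  m <- regmatches(hdr, regexec("^(.*)-(\\d+)$", hdr))
  id <- vapply(seq_along(m), function(i) if (length(m[[i]])) m[[i]][2] else hdr[i],
               character(1))
  count <- vapply(seq_along(m), function(i)
    if (length(m[[i]])) as.numeric(m[[i]][3]) else 1, numeric(1))
  tibble(id = id, seq = unname(as.character(x)), count = count)
}

#' Write a tibble as TSV
#' @param x data frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_file()]
#' @param path input file
#' @return tibble
#' @export
read_tsv_file <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE))
}

#' Write intervals as BED6
#'
#' @param x tibble with chrom, start, end (0-based half-open); optional
#'   `name`, `score`, `strand` columns are used when present
#' @param path output file
#' @return `path`, invisibly
#' @export
write_bed6 <- function(x, path) {
  pick <- function(cands, default) {
    for (nm in cands) if (nm %in% colnames(x)) return(x[[nm]])
    default
  }
  bed <- tibble(chrom = x$chrom, start = x$start, end = x$end,
                name = pick(c("name", "cluster_id", "family", "read_id"), "."),
                score = pick(c("score", "weight", "read_weight"), 0),
                strand = pick("strand", "."))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#' @param path input file
#' @return tibble: chrom, start, end, name, score, strand
#' @export
read_bed6 <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(x)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  as_tibble(x[, 1:6])
}

#' Write gene models as GFF3
#'
#' Minimal GFF3 (standard nine columns; gene and exon features with
#' `ID`/`Parent` attributes).  Coordinates convert from the package's 0-based
#' half-open to GFF3's 1-based closed convention.
#'
#' @param genes tibble: chrom, start, end, strand, gene_id, feature
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  exon_n <- integer(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$feature == "gene") {
      attr <- sprintf("ID=%s", g$gene_id)
    } else {
      if (!g$gene_id %in% names(exon_n)) exon_n[g$gene_id] <- 0L
      exon_n[g$gene_id] <- exon_n[g$gene_id] + 1L
      attr <- sprintf("ID=%s.e%d;Parent=%s", g$gene_id, exon_n[[g$gene_id]], g$gene_id)
    }
    writeLines(sprintf("%s\tpirnascape\t%s\t%d\t%d\t.\t%s\t.\t%s",
                       g$chrom, g$feature, g$start + 1L, g$end, g$strand, attr),
               con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses the standard nine columns, keeping gene and exon features; `Parent`
#' (or `ID` for genes) provides `gene_id`.  Coordinates convert to 0-based
#' half-open.
#'
#' @param path GFF3 file
#' @return tibble: chrom, start, end, strand, gene_id, feature
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(f, function(x) {
    if (length(x) < 9L || !(x[3] %in% c("gene", "exon"))) return(NULL)
    attrs <- strsplit(x[9], ";", fixed = TRUE)[[1]]
    kv <- do.call(rbind, strsplit(attrs, "=", fixed = TRUE))
    get <- function(k) if (k %in% kv[, 1]) kv[kv[, 1] == k, 2][1] else NA_character_
    gid <- if (x[3] == "gene") get("ID") else get("Parent") %||% get("ID")
    tibble(chrom = x[1], start = as.integer(x[4]) - 1L, end = as.integer(x[5]),
           strand = x[7], gene_id = gid, feature = x[3])
  })
  bind_rows(rows)
}

#' Read RepeatMasker .out repeat annotations
#'
#' Parses the whitespace-delimited .out table (three header lines skipped)
#' into the package's repeat-annotation layout.  The class/family column
#' (e.g. `DNA/hAT`, `LINE/L1`, `Simple_repeat`) maps to the controlled
#' vocabulary: DNA, LINE, SINE, LTR, satellite, simple, unknown.  Percent
#' divergence converts to substitutions/site.
#'
#' @param path RepeatMasker .out file
#' @return tibble: chrom, start, end, family, class, superfamily, divergence
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3L, length(lines)))]
  lines <- trimws(lines[nzchar(trimws(lines))])
  f <- strsplit(lines, "\\s+")
  rows <- lapply(f, function(x) {
    if (length(x) < 11L) return(NULL)
    cf <- strsplit(x[11], "/", fixed = TRUE)[[1]]
    cls <- switch(cf[1],
                  DNA = "DNA", LINE = "LINE", SINE = "SINE", LTR = "LTR",
                  Satellite = "satellite", Simple_repeat = "simple",
                  Low_complexity = "simple", "unknown")
    tibble(chrom = x[5], start = as.integer(x[6]) - 1L, end = as.integer(x[7]),
           family = x[10], class = cls,
           superfamily = if (length(cf) > 1L) cf[2] else cf[1],
           divergence = as.numeric(x[2]) / 100)
  })
  bind_rows(rows)
}
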