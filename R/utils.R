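#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n across desc row_number distinct pull rename count
#' @importFrom stats runif setNames uniroot rbinom
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# transitions: A<->G, C<->T; everything else is a transversion
TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; U is treated as T.
#' @param x character vector of DNA/RNA sequences
#' @return character vector
#' @export
revcomp <- function(x) {
  x <- toupper(chartr("U", "T", x))
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# run code under a temporary RNG state; restores the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

rand_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# 0-based half-open interval overlap length
overlap_len <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

stopifnot_scalar_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    abort(sprintf("`%s` must be a single value in [0, 1]", what))
}

# empty alignment tibble with canonical columns
empty_alignments <- function() {
  tibble(read_id = character(), chrom = character(), start = integer(),
         strand = character(), length = integer(), mismatch_pos = character(),
         n_mm = integer(), count = numeric(), weight = numeric())
}

# genomic 5' position (0-based) of an alignment
five_prime_pos <- function(start, strand, length) {
  ifelse(strand == "+", start, start + length - 1L)
}
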