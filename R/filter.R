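#' Exclude reads matching annotated non-piRNA RNAs
#'
#' A read is removed iff its sequence is an exact substring, in either
#' orientation, of any reference sequence (miRNA hairpins, tRNA/rRNA and other
#' annotated ncRNAs, mRNA).  All other reads pass unchanged with their counts.
#' U and T are interchangeable.  Matching strictness is deliberately exact; no
#' mismatches are tolerated.
#'
#' @param reads tibble with columns `id`, `seq`, `count`
#' @param ncrna_refs character vector of reference sequences (may be empty)
#' @return filtered reads tibble
#' @export
exclude_annotated_rna <- function(reads, ncrna_refs = character()) {
  stopifnot(all(c("id", "seq", "count") %in% names(reads)))
  if (length(ncrna_refs) == 0L || nrow(reads) == 0L) return(as_tibble(reads))
  refs <- toupper(chartr("U", "T", ncrna_refs))
  refs <- c(refs, revcomp(refs))
  hay <- paste(refs, collapse = "|")   # one subject; fixed-substring scan per read
  seqs <- toupper(chartr("U", "T", reads$seq))
  hit <- vapply(seqs, function(s) {
    any(stringr::str_detect(refs, stringr::fixed(s)))
  }, logical(1), USE.NAMES = FALSE)
  as_tibble(reads[!hit, , drop = FALSE])
}

#' Keep reads within the piRNA length range
#'
#' Retains reads whose length is within `[min_len, max_len]` inclusive; the
#' defaults select the canonical 24-32 nt piRNA range.
#'
#' @param reads tibble with columns `id`, `seq`, `count`
#' @param min_len,max_len inclusive bounds in nt
#' @return filtered reads tibble
#' @export
length_filter <- function(reads, min_len = 24L, max_len = 32L) {
  stopifnot(all(c("id", "seq", "count") %in% names(reads)))
  if (min_len > max_len) abort("`min_len` must be <= `max_len`")
  L <- nchar(reads$seq)
  as_tibble(reads[L >= min_len & L <= max_len, , drop = FALSE])
}
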