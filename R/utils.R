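# shared helpers

#' Reverse-complement of DNA sequences
#'
#' Vectorised reverse complement for plain character vectors in DNA
#' alphabet (A, C, G, T, N).
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# normalize a nucleotide string: uppercase, U -> T
norm_seq <- function(x) {
  gsub("U", "T", toupper(x), fixed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
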