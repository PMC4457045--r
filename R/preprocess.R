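# Raw reads -> cleaned, collapsed, genome-placed sRNAs.

#' Trim 3' adaptors from raw reads
#'
#' Locates the leftmost exact occurrence of the adaptor's first 8 nt
#' (the full adaptor if shorter) in each read and keeps the 5' portion.
#' Reads without the adaptor, or whose trimmed length falls outside
#' `[min_len, max_len]`, are rejected and counted.
#'
#' @param reads character vector of raw read sequences.
#' @param adaptor 3' adaptor sequence (>= 6 nt).
#' @param min_len,max_len length bounds on the trimmed insert.
#' @return list with `kept` (character vector of trimmed inserts),
#'   `n_no_adaptor`, `n_bad_length`.
#' @export
trim_adaptor <- function(reads, adaptor, min_len = 18L, max_len = 34L) {
  adaptor <- norm_seq(adaptor)
  if (nchar(adaptor) < 6L) stop("adaptor must be >= 6 nt", call. = FALSE)
  probe <- substr(adaptor, 1L, min(8L, nchar(adaptor)))
  reads <- norm_seq(reads)
  pos <- as.integer(regexpr(probe, reads, fixed = TRUE))
  found <- pos > 0L
  trimmed <- substr(reads[found], 1L, pos[found] - 1L)
  ok <- nchar(trimmed) >= min_len & nchar(trimmed) <= max_len
  list(kept = trimmed[ok],
       n_no_adaptor = sum(!found),
       n_bad_length = sum(!ok))
}

#' Collapse a read multiset to unique sequences with counts
#'
#' @param reads character vector of (trimmed) read sequences.
#' @return data.frame `seq`, `count`, `length`; total count equals
#'   `length(reads)`.
#' @export
collapse_reads <- function(reads) {
  if (length(reads) == 0L)
    return(data.frame(seq = character(0), count = integer(0),
                      length = integer(0)))
  tab <- table(reads)
  data.frame(seq = names(tab), count = as.integer(tab),
             length = nchar(names(tab)), stringsAsFactors = FALSE)
}

#' Remove reads matching rRNA references
#'
#' A read is discarded iff it occurs as an exact substring of any rRNA
#' reference sequence or of its reverse complement. With an empty
#' reference set the input is returned unchanged. Idempotent.
#'
#' @param reads collapsed-read data.frame (`seq`, `count`, ...).
#' @param rrna_refs data.frame from [read_fasta()] (or character vector
#'   of sequences); may be empty or NULL.
#' @return the retained rows of `reads`.
#' @export
filter_rrna <- function(reads, rrna_refs = NULL) {
  refs <- if (is.data.frame(rrna_refs)) rrna_refs$seq else rrna_refs
  if (is.null(refs) || length(refs) == 0L || nrow(reads) == 0L) return(reads)
  subjects <- c(norm_seq(refs), revcomp(norm_seq(refs)))
  hit <- vapply(reads$seq, function(s) {
    any(vapply(subjects, function(ref) grepl(s, ref, fixed = TRUE), logical(1L)))
  }, logical(1L))
  out <- reads[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reads per million cleaned library reads
#'
#' @param count read count(s).
#' @param cleaned_total total reads surviving trimming, length bounds and
#'   rRNA filtering in the library.
#' @return numeric RPM.
#' @export
compute_rpm <- function(count, cleaned_total) {
  if (length(cleaned_total) != 1L || is.na(cleaned_total) || cleaned_total <= 0)
    stop("cleaned_total must be a positive scalar", call. = FALSE)
  count * 1e6 / cleaned_total
}

#' Place collapsed reads on a reference by exact full-length matching
#'
#' Enumerates every exact, ungapped, full-length placement of each read
#' on either strand of the reference (Biostrings dictionary matching).
#' Reads with no placement are dropped; reads with more than `max_hits`
#' total placements are dropped entirely; every retained placement
#' carries the read's full count (no fractional weighting for
#' multi-mappers). The leftmost reference coordinate is reported for both
#' strands, 0-based.
#'
#' @param reads collapsed-read data.frame (`seq`, `count`).
#' @param genome data.frame from [read_fasta()] or a named character
#'   vector of reference sequences.
#' @param max_hits drop reads with more placements than this.
#' @return data.frame `seq`, `count`, `length`, `ref_id`, `strand`,
#'   `start`, `hits`, with attribute `dropped` (named counters
#'   `unmapped`, `multihit`, `ambiguous_base`).
#' @export
map_reads <- function(reads, genome, max_hits = 6L) {
  if (is.data.frame(genome)) genome <- stats::setNames(genome$seq, genome$id)
  empty <- data.frame(seq = character(0), count = integer(0),
                      length = integer(0), ref_id = character(0),
                      strand = character(0), start = integer(0),
                      hits = integer(0))
  if (nrow(reads) == 0L)
    return(structure(empty, dropped = c(unmapped = 0L, multihit = 0L,
                                        ambiguous_base = 0L)))
  clean <- grepl("^[ACGT]+$", reads$seq)
  n_ambig <- sum(!clean)
  reads <- reads[clean, , drop = FALSE]
  subjects <- lapply(genome, Biostrings::DNAString)
  pieces <- list()
  for (L in sort(unique(reads$length))) {
    sub <- reads[reads$length == L, , drop = FALSE]
    fwd <- Biostrings::DNAStringSet(sub$seq)
    rev <- Biostrings::reverseComplement(fwd)
    pd_f <- Biostrings::PDict(fwd)
    pd_r <- Biostrings::PDict(rev)
    for (ref in names(subjects)) {
      if (length(subjects[[ref]]) < L) next
      for (str in c("+", "-")) {
        m <- Biostrings::matchPDict(if (str == "+") pd_f else pd_r,
                                    subjects[[ref]])
        st <- Biostrings::startIndex(m)
        idx <- which(lengths(st) > 0L)
        if (length(idx) == 0L) next
        pieces[[length(pieces) + 1L]] <- data.frame(
          seq = rep(sub$seq[idx], lengths(st)[idx]),
          count = rep(sub$count[idx], lengths(st)[idx]),
          length = L,
          ref_id = ref, strand = str,
          start = unlist(st[idx]) - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(pieces) == 0L)
    return(structure(empty, dropped = c(unmapped = nrow(reads), multihit = 0L,
                                        ambiguous_base = n_ambig)))
  aln <- data.table::rbindlist(pieces)
  aln[, hits := .N, by = seq]
  n_multi <- length(unique(aln$seq[aln$hits > max_hits]))
  n_unmapped <- nrow(reads) - length(unique(aln$seq))
  aln <- aln[hits <= max_hits]
  data.table::setorder(aln, ref_id, start, strand)
  structure(as.data.frame(aln),
            dropped = c(unmapped = n_unmapped, multihit = n_multi,
                        ambiguous_base = n_ambig))
}
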