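# Readers and writers for the external formats the pipeline touches.
# All internal coordinates are 0-based half-open; GFF3/SAM/BedGraph are
# converted at the boundary.

#' Read a FASTA file
#'
#' Sequences are uppercased and U is normalised to T, so RNA and DNA
#' inputs are interchangeable downstream.
#'
#' @param path FASTA file.
#' @return data.frame with columns `id`, `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate id ", dup[1L], " in ", path, call. = FALSE)
  seqs <- norm_seq(as.character(set))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence in ", path, call. = FALSE)
  data.frame(id = ids, seq = unname(seqs), stringsAsFactors = FALSE)
}

#' Read a collapsed small-RNA library
#'
#' Accepts either FASTA with headers ending in `_<count>` (the form the
#' public sRNA datasets circulate in) or two-column TSV
#' `sequence<TAB>count`; the dialect is auto-detected from the first
#' non-empty byte. Duplicate sequences are merged by summing counts,
#' with a warning.
#'
#' @param path collapsed-read file.
#' @return data.frame with columns `seq`, `count`, `length`.
#' @export
read_collapsed_reads <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("empty file: ", path, call. = FALSE)
  if (startsWith(first, ">")) {
    fa <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(fa))
    m <- regmatches(ids, regexpr("_([0-9]+)$", ids))
    if (length(m) != length(ids) || any(m == ""))
      stop("collapsed FASTA headers must end in _<count>", call. = FALSE)
    counts <- as.integer(sub("^_", "", m))
    seqs <- norm_seq(as.character(fa))
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "character")
    if (ncol(tab) < 2L)
      stop("collapsed TSV must have columns seq<TAB>count", call. = FALSE)
    if (any(!grepl("^[0-9]+$", tab[[2L]])))
      stop("non-integer count in collapsed TSV", call. = FALSE)
    seqs <- norm_seq(tab[[1L]])
    counts <- as.integer(tab[[2L]])
  }
  if (any(counts < 1L)) stop("read counts must be positive", call. = FALSE)
  if (anyDuplicated(seqs)) {
    warning("duplicate sequences merged by summing counts")
    agg <- rowsum(counts, seqs)
    seqs2 <- rownames(agg)
    counts <- as.integer(agg[, 1L])
    seqs <- seqs2
  }
  data.frame(seq = unname(seqs), count = counts,
             length = nchar(seqs), stringsAsFactors = FALSE)
}

#' Write a collapsed library as FASTA
#'
#' Headers take the `>s<i>_<count>` form accepted back by
#' [read_collapsed_reads()].
#'
#' @param reads data.frame with `seq`, `count`.
#' @param path output path.
#' @export
write_collapsed_fasta <- function(reads, path) {
  lines <- character(0)
  if (nrow(reads) > 0L)
    lines <- as.vector(rbind(sprintf(">s%d_%d", seq_len(nrow(reads)), reads$count),
                             reads$seq))
  writeLines(lines, path)
  invisible(path)
}

# ---- gene models ------------------------------------------------------

#' Construct a gene-model set
#'
#' @param genes data.frame `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open span).
#' @param exons data.frame `gene_id`, `tx_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open), sorted within isoform.
#' @return object of class `phas_genes`.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(genes$start < genes$end), all(exons$start < exons$end))
  exons <- exons[order(exons$gene_id, exons$tx_id, exons$start), , drop = FALSE]
  rownames(genes) <- rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "phas_genes")
}

#' @export
print.phas_genes <- function(x, ...) {
  cat(sprintf("phas_genes: %d genes, %d isoforms, %d exons\n",
              nrow(x$genes), length(unique(paste(x$exons$gene_id, x$exons$tx_id))),
              nrow(x$exons)))
  invisible(x)
}

#' Primary-isoform exons (longest isoform per gene)
#'
#' The primary isoform is the one with the greatest summed exon length;
#' ties resolve to the lexicographically first `tx_id`.
#'
#' @param models a `phas_genes`.
#' @return exon data.frame restricted to one isoform per gene.
#' @export
primary_exons <- function(models) {
  ex <- data.table::as.data.table(models$exons)
  if (nrow(ex) == 0L) return(models$exons)
  len <- ex[, .(tx_len = sum(end - start)), by = .(gene_id, tx_id)]
  data.table::setorder(len, gene_id, -tx_len, tx_id)
  prim <- len[, .SD[1L], by = gene_id]
  out <- ex[prim, on = c("gene_id", "tx_id")]
  data.table::setorder(out, gene_id, start)
  as.data.frame(out[, .(gene_id, tx_id, chrom, strand, start, end)])
}

#' Introns of the primary isoform
#'
#' @param models a `phas_genes`.
#' @return data.frame `gene_id`, `chrom`, `strand`, `start`, `end` of the
#'   gaps between consecutive primary-isoform exons.
#' @export
gene_introns <- function(models) {
  ex <- primary_exons(models)
  out <- list()
  for (g in unique(ex$gene_id)) {
    e <- ex[ex$gene_id == g, , drop = FALSE]
    if (nrow(e) < 2L) next
    out[[g]] <- data.frame(gene_id = g, chrom = e$chrom[1L],
                           strand = e$strand[1L],
                           start = e$end[-nrow(e)], end = e$start[-1L],
                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read gene models from GFF3
#'
#' Understands gene / mRNA (or transcript) / exon features with ID and
#' Parent attributes. Input coordinates are 1-based inclusive and are
#' converted to 0-based half-open. Exons whose Parent is unknown are
#' skipped with a warning; an exon outside its gene span is an error.
#'
#' @param path GFF3 file.
#' @return a `phas_genes` object.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("empty GFF3: ", path, call. = FALSE)
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(f) < 9L) stop("malformed GFF3: expected 9 columns", call. = FALSE)
  feat <- data.frame(chrom = f[[1L]], type = f[[3L]],
                     start = as.integer(f[[4L]]) - 1L, end = as.integer(f[[5L]]),
                     strand = f[[7L]], attr = f[[9L]], stringsAsFactors = FALSE)
  get_attr <- function(a, key) {
    m <- regexpr(paste0("(^|;)", key, "=[^;]+"), a)
    out <- rep(NA_character_, length(a))
    out[m > 0L] <- sub(paste0("^;?", key, "="), "", regmatches(a, m))
    out
  }
  feat$id <- get_attr(feat$attr, "ID")
  feat$parent <- get_attr(feat$attr, "Parent")

  g <- feat[feat$type == "gene", , drop = FALSE]
  if (nrow(g) == 0L) stop("no gene features in ", path, call. = FALSE)
  genes <- data.frame(gene_id = g$id, chrom = g$chrom, strand = g$strand,
                      start = g$start, end = g$end, stringsAsFactors = FALSE)

  tx <- feat[feat$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx2gene <- stats::setNames(tx$parent, tx$id)

  ex <- feat[feat$type == "exon", , drop = FALSE]
  gene_of <- function(p) {
    ifelse(p %in% genes$gene_id, p,
           ifelse(p %in% names(tx2gene), unname(tx2gene[p]), NA_character_))
  }
  keep <- !is.na(ex$parent) & !is.na(gene_of(ex$parent))
  if (any(!keep)) {
    warning(sum(!keep), " exon(s) with missing/unknown Parent skipped")
    ex <- ex[keep, , drop = FALSE]
  }
  exons <- data.frame(gene_id = gene_of(ex$parent),
                      tx_id = ex$parent,
                      chrom = ex$chrom, strand = ex$strand,
                      start = ex$start, end = ex$end, stringsAsFactors = FALSE)
  # genes without annotated exons: the whole span is one exon
  bare <- setdiff(genes$gene_id, exons$gene_id)
  if (length(bare) > 0L) {
    gb <- genes[genes$gene_id %in% bare, , drop = FALSE]
    exons <- rbind(exons, data.frame(gene_id = gb$gene_id, tx_id = gb$gene_id,
                                     chrom = gb$chrom, strand = gb$strand,
                                     start = gb$start, end = gb$end,
                                     stringsAsFactors = FALSE))
  }
  gi <- match(exons$gene_id, genes$gene_id)
  if (any(exons$start < genes$start[gi] | exons$end > genes$end[gi]))
    stop("exon outside gene span", call. = FALSE)
  gene_models(genes, exons)
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gff3()]: emits gene, mRNA and exon features with
#' 1-based inclusive coordinates; read -> write -> read is lossless for
#' intervals and identifiers.
#'
#' @param models a `phas_genes`.
#' @param path output file.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  g <- models$genes
  ex <- models$exons
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, sprintf("%s\tphasr\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$chrom[i], g$start[i] + 1L, g$end[i],
                              g$strand[i], g$gene_id[i]))
    exg <- ex[ex$gene_id == g$gene_id[i], , drop = FALSE]
    for (t in unique(exg$tx_id)) {
      ext <- exg[exg$tx_id == t, , drop = FALSE]
      if (t != g$gene_id[i])
        lines <- c(lines, sprintf("%s\tphasr\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                                  g$chrom[i], min(ext$start) + 1L, max(ext$end),
                                  g$strand[i], t, g$gene_id[i]))
      lines <- c(lines, sprintf("%s\tphasr\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                                ext$chrom, ext$start + 1L, ext$end,
                                ext$strand, t))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- alignments -------------------------------------------------------

#' Import small-RNA alignments from SAM
#'
#' Keeps only ungapped (`<n>M` CIGAR), mismatch-free records (NM tag 0 or
#' absent) and drops reads placed more often than `max_hits` (NH tag, or
#' recomputed by grouping on read name). SAM's 1-based POS is converted
#' to a 0-based leftmost coordinate. Read counts are recovered from
#' `_<count>` name suffixes where present.
#'
#' @param path SAM file with header (needs `@SQ` lines).
#' @param max_hits drop reads with more placements than this.
#' @return data.frame `seq`, `count`, `length`, `ref_id`, `strand`,
#'   `start`, `hits`, with attribute `dropped` (named counters).
#' @export
import_alignments <- function(path, max_hits = 6L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "rname", "strand", "pos",
                                        "cigar", "seq"),
                               tag = c("NH", "NM"))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  n <- length(x$qname)
  if (n == 0L)
    return(structure(data.frame(seq = character(0), count = integer(0),
                                length = integer(0), ref_id = character(0),
                                strand = character(0), start = integer(0),
                                hits = integer(0)),
                     dropped = c(gapped = 0L, mismatched = 0L,
                                 multihit = 0L, unmapped = 0L)))
  mapped <- !is.na(x$pos)
  ungapped <- mapped & grepl("^[0-9]+M$", x$cigar)
  nm <- x$tag$NM %||% rep(NA_integer_, n)
  clean <- ungapped & (is.na(nm) | nm == 0L)
  qname <- x$qname
  nh <- x$tag$NH %||% rep(NA_integer_, n)
  if (anyNA(nh)) {
    tab <- table(qname[clean])
    nh <- ifelse(is.na(nh), as.integer(tab[qname]), nh)
  }
  keep <- clean & nh <= max_hits
  seqs <- as.character(x$seq)[keep]
  strand <- as.character(x$strand)[keep]
  # SAM stores minus-strand reads reverse-complemented; recover read seq
  seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
  cnt <- suppressWarnings(as.integer(sub("^.*_([0-9]+)$", "\\1", qname[keep])))
  cnt[is.na(cnt)] <- 1L
  out <- data.frame(seq = seqs, count = cnt, length = nchar(seqs),
                    ref_id = as.character(x$rname)[keep],
                    strand = strand, start = x$pos[keep] - 1L,
                    hits = as.integer(nh[keep]), stringsAsFactors = FALSE)
  structure(out, dropped = c(gapped = sum(mapped & !ungapped),
                             mismatched = sum(ungapped & !clean),
                             multihit = sum(clean & nh > max_hits),
                             unmapped = sum(!mapped)))
}

# ---- coverage ---------------------------------------------------------

#' Read a BedGraph coverage track
#'
#' @param path BedGraph file; `track`/comment lines are ignored.
#' @return data.frame `chrom`, `start`, `end`, `value` (0-based
#'   half-open, as BedGraph natively is).
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(track|#|browser|\\s*$)", lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), value = numeric(0)))
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  data.frame(chrom = f[[1L]], start = as.integer(f[[2L]]),
             end = as.integer(f[[3L]]), value = as.numeric(f[[4L]]),
             stringsAsFactors = FALSE)
}

# ---- locus outputs ----------------------------------------------------

#' Write called PHAS loci to BED6, GFF3 and a class-summary TSV
#'
#' @param loci locus data.frame as returned by [call_phas_loci()],
#'   optionally annotated with `genomic_class` / `gene_id`.
#' @param prefix output path prefix; writes `<prefix>.bed`,
#'   `<prefix>.gff3`, `<prefix>_summary.tsv`.
#' @return invisible character vector of the three paths.
#' @export
write_locus_outputs <- function(loci, prefix) {
  paths <- c(bed = paste0(prefix, ".bed"), gff = paste0(prefix, ".gff3"),
             tsv = paste0(prefix, "_summary.tsv"))
  cls <- loci$genomic_class %||% rep(NA_character_, nrow(loci))
  gid <- loci$gene_id %||% rep(NA_character_, nrow(loci))
  bed <- character(0)
  gff <- "##gff-version 3"
  if (nrow(loci) > 0L) {
    score <- round(ifelse(is.na(loci$best_score), 0, loci$best_score))
    bed <- sprintf("%s\t%d\t%d\t%s\t%d\t+", loci$ref_id, loci$start,
                   loci$end, loci$locus_id, score)
    gff <- c(gff, sprintf(
      "%s\tphasr\tPHAS_locus\t%d\t%d\t%.3f\t+\t.\tID=%s;pvalue=%.4g;phasing_score=%.4f;class=%s;gene_id=%s",
      loci$ref_id, loci$start + 1L, loci$end,
      ifelse(is.na(loci$best_score), 0, loci$best_score), loci$locus_id,
      loci$best_pvalue, ifelse(is.na(loci$best_score), 0, loci$best_score),
      ifelse(is.na(cls), "NA", cls), ifelse(is.na(gid), "NA", gid)))
  }
  writeLines(bed, paths["bed"])
  writeLines(gff, paths["gff"])
  summ <- summarize_loci(loci)
  utils::write.table(summ, paths["tsv"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
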