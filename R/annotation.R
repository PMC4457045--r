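# Genomic classification of loci, gene-level consolidation, intron
# retention support, and differential phasiRNA production.

locus_footprints <- function(loci) {
  mr <- attr(loci, "member_reads")
  fp <- vector("list", nrow(loci))
  names(fp) <- loci$locus_id
  for (i in seq_len(nrow(loci))) {
    sub <- if (!is.null(mr)) mr[mr$locus_id == loci$locus_id[i], , drop = FALSE]
           else NULL
    fp[[i]] <- if (!is.null(sub) && nrow(sub) > 0L)
      IRanges::reduce(IRanges::IRanges(start = sub$start + 1L,
                                       end = sub$start + sub$length))
    else IRanges::IRanges(start = loci$start[i] + 1L, end = loci$end[i])
  }
  fp
}

#' Classify loci against gene models
#'
#' The footprint used is the union of the locus's phased-read intervals
#' (not the window span, which can overhang an annotation by chance).
#' A locus overlapping no gene span is `intergenic`; otherwise it is
#' assigned to the gene with the larger footprint overlap (ties to the
#' smaller `gene_id`, with a warning) and classified against that gene's
#' primary isoform: footprint entirely exonic -> `exon`, entirely
#' intronic -> `intron`, both -> `exon_intron`.
#'
#' @param loci locus data.frame from [call_phas_loci()].
#' @param models a `phas_genes` object.
#' @return `loci` with `genomic_class` and `gene_id` columns
#'   (member-read attribute preserved).
#' @export
classify_locus <- function(loci, models) {
  loci$genomic_class <- rep(NA_character_, nrow(loci))
  loci$gene_id <- rep(NA_character_, nrow(loci))
  if (nrow(loci) == 0L) return(loci)
  fp <- locus_footprints(loci)
  genes <- models$genes
  pex <- primary_exons(models)
  pint <- gene_introns(models)
  for (i in seq_len(nrow(loci))) {
    g <- genes[genes$chrom == loci$ref_id[i], , drop = FALSE]
    ov <- integer(nrow(g))
    if (nrow(g) > 0L) {
      gr <- IRanges::IRanges(start = g$start + 1L, end = g$end)
      ov <- sum_overlap(fp[[i]], gr)
    }
    if (all(ov == 0L)) { loci$genomic_class[i] <- "intergenic"; next }
    hit <- which(ov == max(ov))
    if (length(which(ov > 0L)) > 1L)
      warning("locus ", loci$locus_id[i], " overlaps multiple genes")
    gid <- sort(g$gene_id[hit])[1L]
    loci$gene_id[i] <- gid
    e <- pex[pex$gene_id == gid, , drop = FALSE]
    it <- pint[pint$gene_id == gid, , drop = FALSE]
    eov <- if (nrow(e)) sum(sum_overlap(fp[[i]],
             IRanges::IRanges(start = e$start + 1L, end = e$end))) else 0L
    iov <- if (nrow(it)) sum(sum_overlap(fp[[i]],
             IRanges::IRanges(start = it$start + 1L, end = it$end))) else 0L
    loci$genomic_class[i] <-
      if (eov > 0L && iov > 0L) "exon_intron"
      else if (iov > 0L) "intron"
      else if (eov > 0L) "exon"
      else "intergenic"
  }
  loci
}

# total overlap width of query ranges with each subject range
sum_overlap <- function(query, subjects) {
  vapply(seq_along(subjects), function(j) {
    sum(IRanges::width(IRanges::pintersect(
      IRanges::findOverlapPairs(query, subjects[j]))))
  }, numeric(1L))
}

#' Combine loci mapping to the same gene
#'
#' Loci sharing a `gene_id` collapse to one record per gene (union
#' extent, minimum P-value, maximum score, summed abundance and window
#' count); intergenic loci pass through untouched. Idempotent.
#'
#' @param loci classified locus data.frame.
#' @return consolidated locus data.frame (member reads re-keyed).
#' @export
merge_by_gene <- function(loci) {
  if (nrow(loci) == 0L) return(loci)
  mr <- attr(loci, "member_reads")
  genic <- !is.na(loci$gene_id)
  keep <- loci[!genic, , drop = FALSE]
  out <- list()
  for (g in unique(loci$gene_id[genic])) {
    s <- loci[genic & loci$gene_id == g, , drop = FALSE]
    rec <- s[1L, , drop = FALSE]
    new_id <- paste0("gene:", g, ":", s$register_len[1L], "nt")
    if (!is.null(mr)) {
      sel <- mr$locus_id %in% s$locus_id
      mr$locus_id[sel] <- new_id
    }
    rec$locus_id <- new_id
    rec$start <- min(s$start); rec$end <- max(s$end)
    rec$best_pvalue <- suppressWarnings(min(s$best_pvalue, na.rm = TRUE))
    rec$best_score <- suppressWarnings(max(s$best_score, na.rm = TRUE))
    rec$window_count <- sum(s$window_count)
    rec$total_count <- sum(s$total_count)
    rec$total_rpm <- if (all(is.na(s$total_rpm))) NA_real_ else
      sum(s$total_rpm, na.rm = TRUE)
    if (nrow(s) > 1L && length(unique(s$genomic_class)) > 1L)
      rec$genomic_class <- "exon_intron"
    out[[length(out) + 1L]] <- rec
  }
  res <- rbind(keep, if (length(out)) do.call(rbind, out))
  res$best_score[!is.finite(res$best_score)] <- NA_real_
  res <- res[order(res$ref_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, member_reads = mr)
}

#' Intron-retention support from RNA-seq coverage
#'
#' For an intron-class locus, the mean RNA-seq coverage over the
#' phasiRNA-producing intron decides whether the intron is excised
#' normally (`bona_fide_intron`: coverage below `low_cov`), retained in
#' the mature transcript (`retained_intron`: coverage at or above
#' `high_cov`), or indeterminate (`unknown`).
#'
#' @param locus one row of a classified locus data.frame.
#' @param models a `phas_genes`.
#' @param coverage BedGraph data.frame from [read_bedgraph()], or NULL.
#' @param cfg a [phas_config()] (supplies `low_cov`, `high_cov`).
#' @return list with `call`, `mean_coverage`, `intron` (interval).
#' @export
intron_retention_support <- function(locus, models, coverage, cfg = phas_config()) {
  ints <- gene_introns(models)
  ints <- ints[!is.na(locus$gene_id) & ints$gene_id == locus$gene_id &
                 ints$end > locus$start & ints$start < locus$end, , drop = FALSE]
  if (nrow(ints) == 0L)
    return(list(call = "unknown", mean_coverage = NA_real_, intron = NULL))
  # the intron with the largest locus overlap is the producing one
  ov <- pmin(ints$end, locus$end) - pmax(ints$start, locus$start)
  intr <- ints[which.max(ov), , drop = FALSE]
  if (is.null(coverage) || nrow(coverage) == 0L)
    return(list(call = "unknown", mean_coverage = NA_real_,
                intron = intr))
  cv <- coverage[coverage$chrom == intr$chrom &
                   coverage$end > intr$start & coverage$start < intr$end, ,
                 drop = FALSE]
  covered <- if (nrow(cv)) sum((pmin(cv$end, intr$end) -
                                  pmax(cv$start, intr$start)) * cv$value) else 0
  mean_cov <- covered / (intr$end - intr$start)
  call <- if (mean_cov < cfg$low_cov) "bona_fide_intron"
          else if (mean_cov >= cfg$high_cov) "retained_intron"
          else "unknown"
  list(call = call, mean_coverage = mean_cov, intron = intr)
}

locus_key <- function(loci) {
  ifelse(!is.na(loci$gene_id), loci$gene_id,
         sprintf("%s:%d-%d", loci$ref_id, loci$start, loci$end))
}

#' Compare phasiRNA production between two libraries
#'
#' Per locus key (gene id where available, coordinates otherwise) the
#' register-length siRNA abundance of the two libraries is compared as
#' `ratio = (rpm_b + eps) / (rpm_a + eps)` with a small RPM pseudocount.
#' Verdicts: `gained_PHAS` / `lost_PHAS` when a locus is called in only
#' one library, `induced` / `suppressed` when the ratio exceeds the
#' fold-change rule (default 5-fold) in either direction, else `stable`.
#' A locus absent from a library's calls gets status `siRNA_only` if its
#' region still carries register-length reads there, `silent` otherwise.
#'
#' @param loci_a,loci_b classified (and typically gene-merged) locus
#'   tables of libraries A and B.
#' @param totals_a,totals_b cleaned library sizes (reads).
#' @param cfg a [phas_config()]; must be the same object/settings for
#'   both libraries.
#' @param aln_a,aln_b optional alignment tables used to measure residual
#'   siRNA abundance at loci the other library called.
#' @return data.frame `key`, `rpm_a`, `rpm_b`, `ratio`, `status_a`,
#'   `status_b`, `verdict`.
#' @export
compare_libraries <- function(loci_a, loci_b, totals_a, totals_b, cfg,
                              aln_a = NULL, aln_b = NULL) {
  ka <- locus_key(loci_a); kb <- locus_key(loci_b)
  keys <- union(ka, kb)
  region_rpm <- function(locus, aln, total) {
    if (is.null(aln) || nrow(aln) == 0L || is.null(total) || total <= 0)
      return(0)
    ph <- register_position(aln$start, aln$strand, cfg$register_len)
    sel <- aln$ref_id == locus$ref_id & aln$length == cfg$register_len &
      ph >= locus$start & ph < locus$end
    compute_rpm(sum(aln$count[sel]), total)
  }
  n <- length(keys)
  rpm_a <- rpm_b <- numeric(n)
  status_a <- status_b <- character(n)
  for (i in seq_len(n)) {
    ia <- match(keys[i], ka); ib <- match(keys[i], kb)
    if (!is.na(ia)) {
      rpm_a[i] <- compute_rpm(loci_a$total_count[ia], totals_a)
      status_a[i] <- "PHAS"
    } else {
      ref <- loci_b[ib, , drop = FALSE]
      rpm_a[i] <- region_rpm(ref, aln_a, totals_a)
      status_a[i] <- if (rpm_a[i] > 0) "siRNA_only" else "silent"
    }
    if (!is.na(ib)) {
      rpm_b[i] <- compute_rpm(loci_b$total_count[ib], totals_b)
      status_b[i] <- "PHAS"
    } else {
      ref <- loci_a[ia, , drop = FALSE]
      rpm_b[i] <- region_rpm(ref, aln_b, totals_b)
      status_b[i] <- if (rpm_b[i] > 0) "siRNA_only" else "silent"
    }
  }
  eps <- cfg$rpm_pseudocount
  ratio <- (rpm_b + eps) / (rpm_a + eps)
  verdict <- ifelse(status_a == "PHAS" & status_b != "PHAS", "lost_PHAS",
             ifelse(status_a != "PHAS" & status_b == "PHAS", "gained_PHAS",
             ifelse(ratio > cfg$fold_change_cutoff, "induced",
             ifelse(ratio < 1 / cfg$fold_change_cutoff, "suppressed",
                    "stable"))))
  data.frame(key = keys, rpm_a = rpm_a, rpm_b = rpm_b, ratio = ratio,
             status_a = status_a, status_b = status_b, verdict = verdict,
             stringsAsFactors = FALSE)
}
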