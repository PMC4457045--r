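# End-to-end orchestration and summary reports.

#' Run the PHAS discovery pipeline end to end
#'
#' Stage order: rRNA filtering -> RPM -> exact mapping -> phased window
#' scan and locus calling (per requested register length) -> genomic
#' classification -> gene-level consolidation -> trigger search ->
#' target prediction. Raw (uncollapsed, untrimmed) input is supported
#' through `adaptor`. Every stage's read counters are recorded in the
#' returned manifest.
#'
#' @param reads collapsed-read data.frame (`seq`, `count`), or a
#'   character vector of raw reads if `adaptor` is given.
#' @param genome named character vector or [read_fasta()] data.frame.
#' @param models a `phas_genes` object, or NULL to skip classification.
#' @param cfg a [phas_config()] (21-nt settings; the 24-nt pass derives
#'   its own register/step from it).
#' @param modes register lengths to call loci for (subset of c(21, 24)).
#' @param adaptor optional 3' adaptor sequence for raw input.
#' @param rrna optional rRNA reference ([read_fasta()] frame).
#' @param mirnas optional known mature miRNA set ([read_fasta()] frame).
#' @param degradome optional degradome 5'-end table (`ref_id`, `pos`,
#'   `count`).
#' @param family_map optional named vector gene_id -> family.
#' @param run_triggers,run_targets logical switches for the two
#'   downstream prediction stages.
#' @return list with `loci` (per mode), `windows` (per mode),
#'   `alignments`, `triggers`, `targets`, `library_total`, `manifest`.
#' @export
run_phas_pipeline <- function(reads, genome, models = NULL,
                              cfg = phas_config(), modes = c(21L),
                              adaptor = NULL, rrna = NULL, mirnas = NULL,
                              degradome = NULL, family_map = NULL,
                              run_triggers = TRUE, run_targets = TRUE) {
  manifest <- list(config = unclass(cfg), seed = cfg$rng_seed,
                   counters = list())
  if (!is.null(adaptor)) {
    tr <- trim_adaptor(reads, adaptor, cfg$min_len, cfg$max_len)
    manifest$counters$raw <- length(reads)
    manifest$counters$no_adaptor <- tr$n_no_adaptor
    manifest$counters$bad_length <- tr$n_bad_length
    reads <- collapse_reads(tr$kept)
  }
  if (!("length" %in% names(reads))) reads$length <- nchar(reads$seq)
  manifest$counters$collapsed_in <- nrow(reads)
  manifest$counters$reads_in <- sum(reads$count)
  reads <- filter_rrna(reads, rrna)
  manifest$counters$after_rrna <- sum(reads$count)
  library_total <- sum(reads$count)
  reads$rpm <- compute_rpm(reads$count, library_total)
  aln <- map_reads(reads, genome, cfg$max_hits)
  manifest$counters$mapping_dropped <- as.list(attr(aln, "dropped"))
  manifest$counters$placements <- nrow(aln)
  aln$rpm <- compute_rpm(aln$count, library_total)
  if (is.data.frame(genome))
    genome <- stats::setNames(genome$seq, genome$id)
  ref_lengths <- vapply(genome, nchar, integer(1L))

  windows <- list(); loci <- list()
  for (R in modes) {
    cfg_m <- if (R == cfg$register_len) cfg else {
      cm <- unclass(cfg); cm$register_len <- as.integer(R)
      cm$window_step <- 3L * as.integer(R)
      do.call(phas_config, cm[names(cm) %in% names(formals(phas_config))])
    }
    w <- scan_windows(aln, ref_lengths, cfg_m)
    l <- call_phas_loci(w, aln, cfg_m, library_total)
    if (!is.null(models)) {
      l <- classify_locus(l, models)
      l <- merge_by_gene(l)
    }
    windows[[as.character(R)]] <- w
    loci[[as.character(R)]] <- l
  }
  manifest$counters$loci <- vapply(loci, nrow, integer(1L))

  triggers <- NULL
  if (run_triggers) {
    pool <- reads[reads$length %in% c(21L, 22L) & reads$rpm > cfg$min_rpm, ,
                  drop = FALSE]
    triggers <- predict_phas_triggers(loci, pool, genome, cfg,
                                      mirnas = mirnas, degradome = degradome)
  }
  targets <- NULL
  if (run_targets && !is.null(models)) {
    pool <- phasirna_pool(loci[["21"]], cfg)
    tx <- gene_transcripts(models, genome)
    targets <- predict_targets(pool, tx, families = family_map, cfg = cfg)
  }
  list(loci = loci, windows = windows, alignments = aln,
       triggers = triggers, targets = targets,
       library_total = library_total, manifest = manifest)
}

#' Trigger search over every called locus
#'
#' Runs [find_triggers()] per locus, annotates candidates against known
#' miRNAs and degradome data, applies [filter_triggers()] and labels
#' each locus's initiation model ([classify_trigger_model()]).
#'
#' @param loci per-mode locus list (or one locus data.frame).
#' @param pool abundant 21/22-nt sRNA data.frame (`seq`, `count`,
#'   `rpm`).
#' @param genome named character vector.
#' @param cfg a [phas_config()].
#' @param mirnas optional known-miRNA frame, `degradome` optional table.
#' @param degradome optional degradome 5'-end table.
#' @return list `candidates` (retained trigger rows) and `models`
#'   (data.frame `locus_id`, `model`).
#' @export
predict_phas_triggers <- function(loci, pool, genome, cfg, mirnas = NULL,
                                  degradome = NULL) {
  if (is.data.frame(loci)) loci <- list(loci)
  cands <- list(); model_rows <- list()
  for (ltab in loci) {
    mr <- attr(ltab, "member_reads")
    if (!is.null(mr) && nrow(mr) > 0L && nrow(ltab) > 0L &&
        !("fp_start" %in% names(ltab))) {
      R <- ltab$register_len[1L]
      mr$ph <- register_position(mr$start, mr$strand, R)
      fp <- data.table::as.data.table(mr)[, .(fp_start = min(ph),
                                              fp_end = max(ph) + ..R),
                                          by = locus_id]
      idx <- match(ltab$locus_id, fp$locus_id)
      ltab$fp_start <- fp$fp_start[idx]
      ltab$fp_end <- fp$fp_end[idx]
    }
    for (i in seq_len(nrow(ltab))) {
      locus <- ltab[i, , drop = FALSE]
      cc <- find_triggers(locus, pool, genome, cfg)
      if (nrow(cc) > 0L) {
        cc$mirna_status <- if (!is.null(mirnas))
          annotate_mirna(cc$seq, mirnas) else "putative"
        cc$degradome <- if (!is.null(degradome))
          degradome_support(rep(locus$ref_id, nrow(cc)), cc$cleavage_pos,
                            degradome, cfg) else "no_data"
        cc <- filter_triggers(cc)
      }
      model_rows[[length(model_rows) + 1L]] <-
        data.frame(locus_id = locus$locus_id,
                   model = classify_trigger_model(cc),
                   stringsAsFactors = FALSE)
      if (nrow(cc) > 0L) cands[[length(cands) + 1L]] <- cc
    }
  }
  list(candidates = if (length(cands)) do.call(rbind, cands) else NULL,
       models = if (length(model_rows)) do.call(rbind, model_rows) else NULL)
}

#' Abundant phasiRNAs of called loci
#'
#' @param loci a called/annotated locus data.frame (21-nt mode).
#' @param cfg a [phas_config()].
#' @return data.frame `seq`, `rpm`, `origin_gene` of unique
#'   register-length member reads with rpm >= `min_rpm`.
#' @export
phasirna_pool <- function(loci, cfg = phas_config()) {
  mr <- attr(loci, "member_reads")
  if (is.null(mr) || nrow(mr) == 0L)
    return(data.frame(seq = character(0), rpm = numeric(0),
                      origin_gene = character(0)))
  mr$origin_gene <- loci$gene_id[match(mr$locus_id, loci$locus_id)] %||%
    NA_character_
  dt <- data.table::as.data.table(mr)
  dt <- dt[, .(rpm = max(rpm), origin_gene = origin_gene[1L]), by = seq]
  out <- as.data.frame(dt[rpm >= cfg$min_rpm])
  out
}

#' Spliced transcript sequences of the primary isoforms
#'
#' @param models a `phas_genes`.
#' @param genome named character vector.
#' @return data.frame `id`, `gene_id`, `seq` (reverse-complemented for
#'   minus-strand genes).
#' @export
gene_transcripts <- function(models, genome) {
  if (is.data.frame(genome)) genome <- stats::setNames(genome$seq, genome$id)
  pex <- primary_exons(models)
  out <- list()
  for (g in unique(pex$gene_id)) {
    e <- pex[pex$gene_id == g, , drop = FALSE]
    sq <- paste(substr(rep(genome[[e$chrom[1L]]], nrow(e)),
                       e$start + 1L, e$end), collapse = "")
    if (e$strand[1L] == "-") sq <- revcomp(sq)
    out[[g]] <- data.frame(id = e$tx_id[1L], gene_id = g, seq = sq,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Class summary of called loci
#'
#' One row per register length with counts by genomic class, the genic
#' subtotal and the total.
#'
#' @param loci locus data.frame (may lack classification).
#' @return data.frame `register_len`, `exon`, `intron`, `exon_intron`,
#'   `genic`, `intergenic`, `total`.
#' @export
summarize_loci <- function(loci) {
  if (is.null(loci) || nrow(loci) == 0L)
    return(data.frame(register_len = integer(0), exon = integer(0),
                      intron = integer(0), exon_intron = integer(0),
                      genic = integer(0), intergenic = integer(0),
                      total = integer(0)))
  cls <- loci$genomic_class %||% rep(NA_character_, nrow(loci))
  out <- list()
  for (R in sort(unique(loci$register_len))) {
    cc <- cls[loci$register_len == R]
    n <- function(k) sum(cc == k, na.rm = TRUE)
    out[[as.character(R)]] <- data.frame(
      register_len = R, exon = n("exon"), intron = n("intron"),
      exon_intron = n("exon_intron"),
      genic = n("exon") + n("intron") + n("exon_intron"),
      intergenic = n("intergenic") + sum(is.na(cc)), total = length(cc))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare two pipeline runs
#'
#' Thin wrapper over [compare_libraries()] that checks the runs used the
#' same reference set.
#'
#' @param run_a,run_b results of [run_phas_pipeline()].
#' @param cfg the shared [phas_config()].
#' @param mode register length to compare (default 21).
#' @return the [compare_libraries()] data.frame.
#' @export
compare_runs <- function(run_a, run_b, cfg, mode = "21") {
  refs_a <- sort(unique(run_a$alignments$ref_id))
  refs_b <- sort(unique(run_b$alignments$ref_id))
  if (!identical(refs_a, refs_b) &&
      length(intersect(refs_a, refs_b)) == 0L)
    stop("runs do not share reference sequences", call. = FALSE)
  compare_libraries(run_a$loci[[mode]], run_b$loci[[mode]],
                    run_a$library_total, run_b$library_total, cfg,
                    aln_a = run_a$alignments, aln_b = run_b$alignments)
}
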