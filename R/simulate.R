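# Seeded synthetic genomes, gene models and small-RNA/degradome
# libraries with planted PHAS loci and full truth tables.

#' Simulation configuration
#'
#' Defaults describe the study conditions every desk-scale run uses: a
#' 200-kb genome, 30 planted 21-nt loci spread over the four genomic
#' classes, 10 duplex cycles per locus with geometric abundance decay,
#' balanced strands, 90% phasing fidelity, ~30% off-phase/background
#' noise reads, 5% rRNA contamination and an even split between one-hit
#' (22-nt trigger) and two-hit (21-nt trigger) initiation.
#'
#' @param genome_len genome length in nt.
#' @param n_genes number of gene models (>= 2; gene 2 is a ~85%-identity
#'   duplicate of gene 1, forming the test gene family).
#' @param n_phas_exonic,n_phas_intronic,n_phas_junction,n_phas_intergenic
#'   planted 21-nt locus counts per genomic class.
#' @param n_phas_24nt planted 24-nt loci (intergenic).
#' @param duplex_cycles phasiRNA duplex cycles per locus.
#' @param base_count read count of the first duplex cycle.
#' @param abundance_decay per-cycle geometric abundance factor.
#' @param strand_balance fraction of each cycle's reads on the sense
#'   strand.
#' @param phasing_fidelity fraction of locus reads left exactly in
#'   phase; the rest are jittered off-phase by 1-10 nt.
#' @param noise_reads count of background reads drawn from random
#'   genomic positions (lengths 18-26); `NA` picks the count making
#'   noise ~30% of unique reads.
#' @param rrna_fraction fraction of the raw library drawn from the rRNA
#'   stub.
#' @param trigger_len_mix probability a 21-nt locus uses the one-hit
#'   22-nt trigger model (vs two-hit 21-nt).
#' @param library_depth target raw library depth; `NA` derives it from
#'   the planted counts.
#' @param seed RNG seed; fixed seed gives byte-identical outputs.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(genome_len = 200000L, n_genes = 26L,
                       n_phas_exonic = 10L, n_phas_intronic = 8L,
                       n_phas_junction = 6L, n_phas_intergenic = 6L,
                       n_phas_24nt = 0L, duplex_cycles = 10L,
                       base_count = 40L, abundance_decay = 0.8,
                       strand_balance = 0.5, phasing_fidelity = 0.9,
                       noise_reads = NA_integer_, rrna_fraction = 0.05,
                       trigger_len_mix = 0.5, library_depth = NA_integer_,
                       seed = 42L) {
  cfg <- list(genome_len = as.integer(genome_len), n_genes = as.integer(n_genes),
              n_phas_exonic = as.integer(n_phas_exonic),
              n_phas_intronic = as.integer(n_phas_intronic),
              n_phas_junction = as.integer(n_phas_junction),
              n_phas_intergenic = as.integer(n_phas_intergenic),
              n_phas_24nt = as.integer(n_phas_24nt),
              duplex_cycles = as.integer(duplex_cycles),
              base_count = as.integer(base_count),
              abundance_decay = abundance_decay,
              strand_balance = strand_balance,
              phasing_fidelity = phasing_fidelity,
              noise_reads = noise_reads, rrna_fraction = rrna_fraction,
              trigger_len_mix = trigger_len_mix,
              library_depth = library_depth, seed = as.integer(seed))
  fr <- c("abundance_decay", "strand_balance", "phasing_fidelity",
          "rrna_fraction", "trigger_len_mix")
  for (f in fr) if (cfg[[f]] < 0 || cfg[[f]] > 1)
    stop(f, " must lie in [0, 1]", call. = FALSE)
  if (cfg$duplex_cycles < 1L) stop("duplex_cycles must be >= 1", call. = FALSE)
  structure(cfg, class = "sim_config")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Generate a synthetic genome with gene models and a gene family
#'
#' Builds a seeded random genome carrying `n_genes` non-overlapping
#' multi-exon genes on one chromosome. Gene 2 is a structural duplicate
#' of gene 1 whose sequence is copied at ~85% identity, giving a
#' two-member gene family for same-family target tests; all other genes
#' are singleton families.
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` (named character vector), `models`
#'   (`phas_genes`), `family_map` (named character vector
#'   gene_id -> family).
#' @export
make_genome <- function(cfg = sim_config()) {
  needed <- cfg$n_phas_exonic + cfg$n_phas_junction + cfg$n_phas_intronic
  if (cfg$n_genes == 0L && needed > 0L)
    stop("genic loci requested but n_genes = 0", call. = FALSE)
  set.seed(cfg$seed)
  genome <- rand_dna(cfg$genome_len)
  genes <- list(); exons <- list()
  cursor <- 1200L
  struct1 <- NULL
  for (i in seq_len(cfg$n_genes)) {
    gid <- sprintf("g%03d", i)
    if (i == 2L && !is.null(struct1)) {
      st <- struct1 # structural copy of gene 1
    } else {
      n_ex <- sample(2:4, 1L)
      st <- list(ex_len = sample(400:900, n_ex, replace = TRUE),
                 in_len = sample(300:520, max(0L, n_ex - 1L), replace = TRUE))
      if (i == 1L) struct1 <- st
    }
    span <- sum(st$ex_len) + sum(st$in_len)
    if (cursor + span + 1500L > cfg$genome_len)
      stop(sprintf("genome too small: needs >= %d nt for %d genes",
                   cursor + span + 1500L, cfg$n_genes), call. = FALSE)
    ex_start <- cursor + c(0L, cumsum(st$ex_len[-length(st$ex_len)] +
                                        st$in_len))
    exons[[gid]] <- data.frame(gene_id = gid, tx_id = paste0(gid, ".t1"),
                               chrom = "chr1", strand = "+",
                               start = as.integer(ex_start),
                               end = as.integer(ex_start + st$ex_len),
                               stringsAsFactors = FALSE)
    genes[[gid]] <- data.frame(gene_id = gid, chrom = "chr1", strand = "+",
                               start = as.integer(cursor),
                               end = as.integer(cursor + span),
                               stringsAsFactors = FALSE)
    cursor <- as.integer(cursor + span + sample(900:2000, 1L))
  }
  genes <- do.call(rbind, genes); exons <- do.call(rbind, exons)
  rownames(genes) <- rownames(exons) <- NULL
  # duplicate gene 1's sequence into gene 2 at ~85% identity
  family_map <- stats::setNames(paste0("fam_", genes$gene_id), genes$gene_id)
  if (cfg$n_genes >= 2L) {
    g1 <- genes[1L, ]; g2 <- genes[2L, ]
    copy <- mutate_seq(substr(genome, g1$start + 1L, g1$end), 0.15)
    genome <- paste0(substr(genome, 1L, g2$start),
                     copy,
                     substr(genome, g2$end + 1L, nchar(genome)))
    family_map[genes$gene_id[2L]] <- family_map[genes$gene_id[1L]]
  }
  list(genome = c(chr1 = genome),
       models = gene_models(genes, exons),
       family_map = family_map)
}

#' Plant one phased-siRNA locus into a genome
#'
#' Writes the trigger target site(s) into the sequence (for the two-hit
#' model the 5' site is copied to the locus 3' end so one 21-nt sRNA
#' hits both), then emits `duplex_cycles` successive sense reads at
#' `cleavage + i * register_len` and antisense duplex partners at a
#' leftmost offset of -2 (the 2-nt 3' overhang), with geometrically
#' decaying counts. A `1 - phasing_fidelity` fraction of reads is
#' jittered off-phase by 1-10 nt.
#'
#' @param genome_seq chromosome sequence (single string).
#' @param start 0-based cleavage coordinate where phasing begins.
#' @param register_len 21 or 24.
#' @param model "one_hit_22" or "two_hit".
#' @param cfg a [sim_config()].
#' @param locus_id identifier used in the truth table.
#' @param locus_class genomic class recorded in the truth table.
#' @return list `genome_seq` (edited), `reads` (data.frame `seq`,
#'   `count`, `provenance`), `truth_locus` (one row), `truth_triggers`
#'   (rows with trigger seq, cleavage, model), `cleavages` (integer
#'   vector).
#' @export
plant_phas_locus <- function(genome_seq, start, register_len, model, cfg,
                             locus_id = "phas1", locus_class = "intergenic") {
  R <- as.integer(register_len)
  nc <- cfg$duplex_cycles
  c0 <- as.integer(start)
  end <- c0 + nc * R
  tlen <- if (model == "one_hit_22") 22L else 21L
  if (c0 - (tlen - 10L) < 0L || end + 12L > nchar(genome_seq))
    stop("site too short for locus plus trigger flanks", call. = FALSE)
  cleavages <- c0
  if (model == "two_hit") {
    # copy the 5' site so the same 21-nt sRNA hits the 3' end in phase
    c2 <- end
    site <- substr(genome_seq, c0 - 11L + 1L, c0 + 10L)
    genome_seq <- paste0(substr(genome_seq, 1L, c2 - 11L), site,
                         substr(genome_seq, c2 + 10L + 1L,
                                nchar(genome_seq)))
    cleavages <- c(c0, c2)
  }
  t0 <- c0 - (tlen - 10L)
  trig_seq <- revcomp(substr(genome_seq, t0 + 1L, t0 + tlen))
  reads <- list()
  emit <- function(s, strand, count, prov) {
    Re <- R
    if (stats::runif(1L) > cfg$phasing_fidelity) {
      # degradation product: off-register position and degraded length
      s <- s + sample(c(-10:-1, 1:10), 1L)
      Re <- sample(18:26, 1L)
      prov <- "offphase"
    }
    sq <- if (strand == "+") substr(genome_seq, s + 1L, s + Re) else
      revcomp(substr(genome_seq, s + 1L, s + Re))
    data.frame(seq = sq, count = count, provenance = prov,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nc) - 1L) {
    ci <- max(1L, round(cfg$base_count * cfg$abundance_decay^i))
    cs <- max(1L, round(ci * cfg$strand_balance))
    ca <- max(1L, ci - cs)
    s <- c0 + i * R
    reads[[length(reads) + 1L]] <- emit(s, "+", cs, paste0(locus_id, ":phased"))
    reads[[length(reads) + 1L]] <- emit(s - 2L, "-", ca,
                                        paste0(locus_id, ":phased"))
  }
  reads <- do.call(rbind, reads)
  reads$provenance[reads$provenance == "offphase"] <-
    paste0(locus_id, ":offphase")
  truth_locus <- data.frame(locus_id = locus_id, class = locus_class,
                            chrom = "chr1", start = c0, end = end,
                            register_len = R, phase_offset = c0 %% R,
                            model = model, trigger_seq = trig_seq,
                            stringsAsFactors = FALSE)
  truth_triggers <- data.frame(locus_id = locus_id, seq = trig_seq,
                               trigger_len = tlen, cleavage = cleavages,
                               end = c("5prime", "3prime")[seq_along(cleavages)],
                               model = model, stringsAsFactors = FALSE)
  list(genome_seq = genome_seq, reads = reads, truth_locus = truth_locus,
       truth_triggers = truth_triggers, cleavages = cleavages)
}

pick_locus_sites <- function(built, cfg) {
  models <- built$models
  pex <- primary_exons(models)
  pint <- gene_introns(models)
  genes <- models$genes
  span21 <- 21L * cfg$duplex_cycles
  sites <- list()
  add <- function(start, class, R) {
    sites[[length(sites) + 1L]] <<- data.frame(start = as.integer(start),
                                               class = class,
                                               register_len = as.integer(R),
                                               stringsAsFactors = FALSE)
  }
  used_genes <- character(0)
  take_gene <- function(pool) {
    cand <- setdiff(pool, used_genes)
    if (length(cand) == 0L) stop("not enough genes for requested loci",
                                 call. = FALSE)
    used_genes <<- c(used_genes, cand[1L])
    cand[1L]
  }
  # exonic: first one goes into gene 1 so family-member targeting is testable
  ex_ok <- pex[pex$end - pex$start >= span21 + 40L, , drop = FALSE]
  # avoid the mutated duplicate as a host (its reads are identical questions)
  ex_pool <- unique(ex_ok$gene_id[ex_ok$gene_id != genes$gene_id[2L]])
  ex_pool <- c(intersect(genes$gene_id[1L], ex_pool),
               setdiff(ex_pool, genes$gene_id[1L]))
  for (i in seq_len(cfg$n_phas_exonic)) {
    g <- take_gene(ex_pool)
    e <- ex_ok[ex_ok$gene_id == g, , drop = FALSE][1L, ]
    add(e$start + 15L, "exon", 21L)
  }
  in_ok <- pint[pint$end - pint$start >= span21 + 50L, , drop = FALSE]
  for (i in seq_len(cfg$n_phas_intronic)) {
    g <- take_gene(setdiff(unique(in_ok$gene_id), genes$gene_id[2L]))
    it <- in_ok[in_ok$gene_id == g, , drop = FALSE][1L, ]
    add(it$start + 25L, "intron", 21L)
  }
  # junction: phasing starts inside an exon and runs across its 3' boundary
  for (i in seq_len(cfg$n_phas_junction)) {
    g <- take_gene(setdiff(unique(in_ok$gene_id), genes$gene_id[2L]))
    it <- in_ok[in_ok$gene_id == g, , drop = FALSE][1L, ]
    add(it$start - 100L, "exon_intron", 21L)
  }
  # intergenic: gaps between gene spans
  gaps_start <- c(600L, genes$end + 300L)
  gaps_end <- c(genes$start - 300L, cfg$genome_len - 600L)
  ok <- which(gaps_end - gaps_start >= 24L * cfg$duplex_cycles + 100L)
  need_ig <- cfg$n_phas_intergenic + cfg$n_phas_24nt
  if (length(ok) < need_ig) stop("not enough intergenic space", call. = FALSE)
  for (i in seq_len(cfg$n_phas_intergenic))
    add(gaps_start[ok[i]] + 40L, "intergenic", 21L)
  for (i in seq_len(cfg$n_phas_24nt))
    add(gaps_start[ok[cfg$n_phas_intergenic + i]] + 40L, "intergenic", 24L)
  do.call(rbind, sites)
}

#' Build a complete synthetic small-RNA library with truth tables
#'
#' Generates the genome ([make_genome()]), plants every requested PHAS
#' locus with its trigger ([plant_phas_locus()]), adds trigger sRNAs,
#' genomic background noise reads, rRNA-stub contaminants and degradome
#' 5'-end reads at every true cleavage site, and collapses the library.
#'
#' @param cfg a [sim_config()].
#' @return list `genome`, `models`, `family_map`, `reads` (collapsed,
#'   with provenance), `rrna` (reference stub data.frame), `degradome`
#'   (data.frame `ref_id`, `pos`, `count`, `seq`), `truth` (list
#'   `loci`, `triggers`), `cfg`.
#' @export
make_library <- function(cfg = sim_config()) {
  built <- make_genome(cfg)
  sites <- pick_locus_sites(built, cfg)
  gseq <- built$genome[["chr1"]]
  all_reads <- list(); truth_loci <- list(); truth_triggers <- list()
  degradome <- list()
  for (i in seq_len(nrow(sites))) {
    R <- sites$register_len[i]
    model <- if (R == 24L) "one_hit_22" else
      if (stats::runif(1L) < cfg$trigger_len_mix) "one_hit_22" else "two_hit"
    lid <- sprintf("truth%02d_%s_%dnt", i, sites$class[i], R)
    pl <- plant_phas_locus(gseq, sites$start[i], R, model, cfg,
                           locus_id = lid, locus_class = sites$class[i])
    gseq <- pl$genome_seq
    all_reads[[length(all_reads) + 1L]] <- pl$reads
    # the trigger itself is an abundant library member
    all_reads[[length(all_reads) + 1L]] <-
      data.frame(seq = pl$truth_triggers$seq[1L], count = 60L,
                 provenance = paste0(lid, ":trigger"),
                 stringsAsFactors = FALSE)
    truth_loci[[length(truth_loci) + 1L]] <- pl$truth_locus
    truth_triggers[[length(truth_triggers) + 1L]] <- pl$truth_triggers
    degradome[[length(degradome) + 1L]] <-
      data.frame(ref_id = "chr1", pos = pl$cleavages, count = 5L,
                 seq = substr(gseq, pl$cleavages + 1L, pl$cleavages + 20L),
                 stringsAsFactors = FALSE)
  }
  planted <- do.call(rbind, all_reads)
  # background: reads from random genomic positions, lengths 18-26
  n_noise <- cfg$noise_reads
  if (is.na(n_noise))
    n_noise <- round(0.3 / 0.7 * nrow(planted))
  if (n_noise > 0L) {
    ln <- sample(18:26, n_noise, replace = TRUE)
    st <- sample.int(cfg$genome_len - 30L, n_noise, replace = TRUE)
    strand <- sample(c("+", "-"), n_noise, replace = TRUE)
    sq <- substr(rep(gseq, n_noise), st, st + ln - 1L)
    sq[strand == "-"] <- revcomp(sq[strand == "-"])
    all_reads[[length(all_reads) + 1L]] <-
      data.frame(seq = sq, count = sample(1:3, n_noise, replace = TRUE),
                 provenance = "noise", stringsAsFactors = FALSE)
  }
  # rRNA stub contamination
  rrna_seq <- rand_dna(1200L)
  lib <- do.call(rbind, all_reads)
  if (cfg$rrna_fraction > 0) {
    depth <- if (is.na(cfg$library_depth))
      round(sum(lib$count) / (1 - cfg$rrna_fraction)) else cfg$library_depth
    n_rrna <- stats::rbinom(1L, depth, cfg$rrna_fraction)
    if (n_rrna > 0L) {
      nwin <- 40L
      st <- sample.int(1200L - 24L, nwin, replace = TRUE)
      per <- stats::rmultinom(1L, n_rrna, rep(1, nwin))[, 1L]
      keep <- per > 0L
      lib <- rbind(lib, data.frame(
        seq = substr(rep(rrna_seq, sum(keep)), st[keep], st[keep] + 20L),
        count = per[keep], provenance = "rrna", stringsAsFactors = FALSE))
    }
  }
  agg <- data.table::as.data.table(lib)[, .(count = sum(count),
      provenance = provenance[1L]), by = seq]
  reads <- as.data.frame(agg)
  reads$length <- nchar(reads$seq)
  built$genome[["chr1"]] <- gseq
  list(genome = built$genome, models = built$models,
       family_map = built$family_map, reads = reads,
       rrna = data.frame(id = "rRNA_stub_synthetic", seq = rrna_seq,
                         stringsAsFactors = FALSE),
       degradome = do.call(rbind, degradome),
       truth = list(loci = do.call(rbind, truth_loci),
                    triggers = do.call(rbind, truth_triggers)),
       cfg = cfg)
}

#' Recovery of planted loci by called loci
#'
#' A truth locus is recovered iff some called locus of the same register
#' length overlaps at least `min_frac` of it; a called locus matching no
#' truth locus under the same rule is a false positive.
#'
#' @param called locus data.frame from [call_phas_loci()].
#' @param truth_loci truth table (`truth$loci` of [make_library()]).
#' @param min_frac minimum overlap as a fraction of the truth extent.
#' @return list `sensitivity`, `precision`, `by_class` (per-class
#'   recovery data.frame), `recovered` (logical per truth locus),
#'   `called_true` (logical per called locus).
#' @export
score_recovery <- function(called, truth_loci, min_frac = 0.5) {
  nt <- nrow(truth_loci); ncl <- nrow(called)
  recovered <- logical(nt); called_true <- logical(max(ncl, 0L))
  for (i in seq_len(nt)) {
    tl <- truth_loci[i, ]
    if (ncl == 0L) next
    ov <- pmin(called$end, tl$end) - pmax(called$start, tl$start)
    hit <- called$ref_id == tl$chrom & called$register_len == tl$register_len &
      ov >= min_frac * (tl$end - tl$start)
    recovered[i] <- any(hit)
    called_true[hit] <- TRUE
  }
  by_class <- stats::aggregate(recovered,
                               by = list(class = truth_loci$class), FUN = mean)
  names(by_class)[2L] <- "sensitivity"
  list(sensitivity = if (nt > 0L) mean(recovered) else NA_real_,
       precision = if (ncl > 0L) mean(called_true) else NA_real_,
       by_class = by_class, recovered = recovered,
       called_true = called_true)
}
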