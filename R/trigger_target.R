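# Trigger prediction, phase consistency, miRNA annotation, hairpin
# evaluation, phasiRNA target prediction and degradome validation.

#' Score an sRNA against a target window
#'
#' Finds the best duplex (ungapped or with a single 1-nt bulge on either
#' side) between the sRNA and the target window under plant-target
#' penalties: mismatch 1.0, G:U wobble 0.5, bulge 2.0, all doubled at
#' sRNA positions 2-13 (5'->3'). The predicted cleavage position is the
#' target coordinate paired to sRNA position 10 (the canonical plant
#' slicing rule: cut between positions 10 and 11).
#'
#' @param srna sRNA sequence (18-26 nt, 5'->3').
#' @param target target window sequence (5'->3').
#' @param cutoff report only duplexes with score at or below this; use
#'   `Inf` for the unconditional best.
#' @return single-row data.frame `t_start`, `score`, `cleavage` (both
#'   0-based within `target`), `variant`, `bulge` — or a 0-row frame if
#'   the window is shorter than the sRNA or no duplex meets the cutoff.
#' @export
align_srna_target <- function(srna, target, cutoff = Inf, weighted = TRUE,
                              wobble = 0.5) {
  srna <- norm_seq(srna); target <- norm_seq(target)
  if (nchar(srna) < 18L || nchar(srna) > 26L)
    stop("sRNA must be 18-26 nt", call. = FALSE)
  hits <- duplex_hits(srna, target, cutoff, weighted, wobble)
  if (nrow(hits) == 0L) return(hits)
  hits[order(hits$score, hits$t_start, hits$variant), ][1L, , drop = FALSE]
}

#' All duplex hits of an sRNA on a target at or below a score cutoff
#'
#' Same scoring as [align_srna_target()]; hits sharing a cleavage
#' position are collapsed to the minimal-score registration.
#'
#' @inheritParams align_srna_target
#' @param weighted apply the 2x weighting at sRNA positions 2-13
#'   (default); `FALSE` scores all positions uniformly.
#' @param wobble penalty for a G:U pair; 1 treats wobbles as plain
#'   mismatches, which makes the score strand-symmetric.
#' @return data.frame `t_start`, `score`, `cleavage`, `variant`, `bulge`.
#' @export
duplex_hits <- function(srna, target, cutoff = Inf, weighted = TRUE,
                        wobble = 0.5) {
  cut_eff <- if (is.finite(cutoff)) cutoff else
    2 * sum(ifelse(seq_len(nchar(srna)) %in% 2:13, 2, 1))
  h <- duplex_hits_cpp(norm_seq(srna), norm_seq(target), cut_eff,
                       weighted, wobble)
  if (nrow(h) == 0L) return(h)
  h <- h[order(h$cleavage, h$score, h$variant), , drop = FALSE]
  h <- h[!duplicated(h$cleavage), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Phase relation of a cleavage site to a locus
#'
#' @param cleavage_pos 0-based genomic cleavage coordinate(s).
#' @param locus one locus row (needs `phase_offset`, `register_len`).
#' @return "in_phase" where `cleavage_pos` falls in the locus's residue
#'   class modulo the register length, else "out_of_phase".
#' @export
phase_consistency <- function(cleavage_pos, locus) {
  ifelse((cleavage_pos - locus$phase_offset) %% locus$register_len == 0L,
         "in_phase", "out_of_phase")
}

#' Search for phasiRNA triggers around a locus
#'
#' Scans the 200-nt flanks on both sides of the locus (plus the locus
#' ends themselves) with every pool sRNA and keeps duplexes with score
#' at most `trigger_score_cutoff`. The pool must already be restricted
#' to abundant (>= `min_rpm`) 21- and 22-nt sRNAs.
#'
#' @param locus one locus row.
#' @param pool data.frame `seq`, `count`, `rpm` of candidate trigger
#'   sRNAs (21/22 nt, abundant).
#' @param genome named character vector (or [read_fasta()] frame).
#' @param cfg a [phas_config()].
#' @return data.frame `locus_id`, `seq`, `trigger_len`, `rpm`, `end`
#'   ("5prime"/"3prime"), `score`, `cleavage_pos` (genomic, 0-based),
#'   `phase_relation`, `truncated_flank`.
#' @export
find_triggers <- function(locus, pool, genome, cfg = phas_config()) {
  if (is.data.frame(genome)) genome <- stats::setNames(genome$seq, genome$id)
  ref <- genome[[locus$ref_id]]
  L <- nchar(ref)
  out <- list()
  # anchor the flanks on the phased-read footprint where known: the
  # window-grid union can overhang the phased structure by up to two
  # window steps, which would bury the cleavage site inside the locus
  a_start <- locus$fp_start %||% locus$start
  a_end <- locus$fp_end %||% locus$end
  if (is.na(a_start)) a_start <- locus$start
  if (is.na(a_end)) a_end <- locus$end
  flanks <- list(
    `5prime` = c(max(0L, a_start - cfg$trigger_flank),
                 min(L, a_start + 26L)),
    `3prime` = c(max(0L, a_end - 26L),
                 min(L, a_end + cfg$trigger_flank)))
  truncated <- (a_start - cfg$trigger_flank < 0L) ||
    (a_end + cfg$trigger_flank > L)
  for (side in names(flanks)) {
    w <- flanks[[side]]
    win <- substr(ref, w[1L] + 1L, w[2L])
    for (i in seq_len(nrow(pool))) {
      h <- duplex_hits(pool$seq[i], win, cfg$trigger_score_cutoff)
      if (nrow(h) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        locus_id = locus$locus_id, seq = pool$seq[i],
        trigger_len = nchar(pool$seq[i]),
        rpm = pool$rpm[i] %||% NA_real_,
        end = side, score = h$score,
        cleavage_pos = w[1L] + h$cleavage,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(locus_id = character(0), seq = character(0),
                      trigger_len = integer(0), rpm = numeric(0),
                      end = character(0), score = numeric(0),
                      cleavage_pos = integer(0),
                      phase_relation = character(0),
                      truncated_flank = logical(0)))
  res <- do.call(rbind, out)
  # the same site can be reached from both scan windows; keep one record
  res <- res[!duplicated(res[, c("seq", "cleavage_pos")]), , drop = FALSE]
  res$phase_relation <- phase_consistency(res$cleavage_pos, locus)
  res$truncated_flank <- truncated
  rownames(res) <- NULL
  res
}

#' Annotate an sRNA against known mature miRNAs
#'
#' @param srna sRNA sequence(s).
#' @param known data.frame from [read_fasta()] (mature miRNA sequences)
#'   or character vector; may be empty.
#' @return "known" where some entry matches with length difference at
#'   most 1 and at most 2 mismatches (best sliding registration), else
#'   "putative".
#' @export
annotate_mirna <- function(srna, known) {
  refs <- if (is.data.frame(known)) known$seq else known
  refs <- norm_seq(refs %||% character(0))
  vapply(norm_seq(srna), function(s) {
    for (r in refs) {
      if (abs(nchar(s) - nchar(r)) > 1L) next
      short <- if (nchar(s) <= nchar(r)) s else r
      long <- if (nchar(s) <= nchar(r)) r else s
      for (off in 0:(nchar(long) - nchar(short))) {
        seg <- substr(long, off + 1L, off + nchar(short))
        mm <- sum(utf8ToInt(seg) != utf8ToInt(short))
        if (mm <= 2L) return("known")
      }
    }
    "putative"
  }, character(1L), USE.NAMES = FALSE)
}

#' Keep plausible triggers
#'
#' In-phase candidates are kept. Out-of-phase candidates survive only if
#' they are known miRNAs and either whitelisted (established trigger
#' families) or degradome-validated; everything else is dropped.
#'
#' @param cands trigger candidates with `phase_relation`,
#'   `mirna_status`, optionally `degradome`, `whitelisted` columns.
#' @return retained rows with a `kept_reason` column.
#' @export
filter_triggers <- function(cands) {
  if (nrow(cands) == 0L) { cands$kept_reason <- character(0); return(cands) }
  wl <- cands$whitelisted %||% rep(FALSE, nrow(cands))
  dg <- cands$degradome %||% rep("no_data", nrow(cands))
  ms <- cands$mirna_status %||% rep("putative", nrow(cands))
  keep_in <- cands$phase_relation == "in_phase"
  keep_out <- cands$phase_relation == "out_of_phase" & ms == "known" &
    (wl | dg == "validated")
  out <- cands[keep_in | keep_out, , drop = FALSE]
  out$kept_reason <- ifelse(out$phase_relation == "in_phase", "in_phase",
                            "known_confirmed")
  rownames(out) <- NULL
  out
}

#' Classify the trigger model of a locus
#'
#' Two distinct 21-nt hit sites (same or different sRNAs) indicate the
#' two-hit model; a single 22-nt hit the one-hit model; a single 21-nt
#' hit stays unclassified.
#'
#' @param cands retained trigger candidates of one locus.
#' @return one of "two_hit", "one_hit_22", "unclassified", "none".
#' @export
classify_trigger_model <- function(cands) {
  if (nrow(cands) == 0L) return("none")
  sites21 <- unique(cands$cleavage_pos[cands$trigger_len == 21L])
  sites22 <- unique(cands$cleavage_pos[cands$trigger_len == 22L])
  if (length(sites21) >= 2L) "two_hit"
  else if (length(sites22) >= 1L && length(sites21) == 0L) "one_hit_22"
  else if (length(sites22) >= 1L) "one_hit_22"
  else "unclassified"
}

#' Evaluate whether an sRNA could derive from a miRNA-like hairpin
#'
#' Extracts +/-150 nt of genomic context around each placement, folds it
#' with the ViennaRNA `RNAfold` command-line program (the optional
#' folding engine), and requires the sRNA to sit in one arm of a
#' stem-loop with at least 16 of its positions paired and at most one
#' internal loop of 4 nt or more inside the sRNA region.
#'
#' @param srna sRNA sequence.
#' @param genome named character vector or [read_fasta()] frame.
#' @param placements data.frame `ref_id`, `strand`, `start` of the
#'   sRNA's genomic placements.
#' @return character vector per placement: "plausible_mirna",
#'   "not_hairpin", or "no_engine" when RNAfold is unavailable.
#' @export
evaluate_hairpin <- function(srna, genome, placements) {
  if (is.data.frame(genome)) genome <- stats::setNames(genome$seq, genome$id)
  if (Sys.which("RNAfold") == "")
    return(rep("no_engine", nrow(placements)))
  srna <- norm_seq(srna)
  L <- nchar(srna)
  vapply(seq_len(nrow(placements)), function(i) {
    ref <- genome[[placements$ref_id[i]]]
    s <- placements$start[i]
    a <- max(0L, s - 150L); b <- min(nchar(ref), s + L + 150L)
    ctx <- substr(ref, a + 1L, b)
    if (placements$strand[i] == "-") ctx <- revcomp(ctx)
    fold <- system2("RNAfold", args = "--noPS", input = ctx, stdout = TRUE)
    db <- sub("\\s.*$", "", fold[2L])
    off <- if (placements$strand[i] == "-") (b - (s + L)) else (s - a)
    region <- substr(db, off + 1L, off + L)
    paired <- sum(strsplit(region, "")[[1L]] %in% c("(", ")"))
    big_loops <- attr(gregexpr("\\.{4,}", region)[[1L]], "match.length")
    n_big <- if (big_loops[1L] == -1L) 0L else length(big_loops)
    one_arm <- !(grepl("(", region, fixed = TRUE) &&
                   grepl(")", region, fixed = TRUE))
    if (paired >= 16L && n_big <= 1L && one_arm) "plausible_mirna"
    else "not_hairpin"
  }, character(1L))
}

#' Predict phasiRNA targets across a transcriptome
#'
#' Every abundant phasiRNA (register-length member reads of positive
#' loci at or above `min_rpm`) is scanned against each transcript in
#' both orientations (the phasing precursor passes through a
#' double-stranded intermediate, so phasiRNAs of either polarity are
#' searched) and hits with score at most `target_score_cutoff` are
#' reported; hits at or below `stringent_target_cutoff` carry a
#' stringent flag.
#'
#' @param phasirnas data.frame `seq`, `rpm`, `origin_gene` (NA for
#'   intergenic loci), already filtered to register length and
#'   abundance.
#' @param transcripts data.frame `id`, `seq` (spliced transcripts), with
#'   optional `gene_id` column (defaults to `id`).
#' @param families named character vector gene_id -> family id; missing
#'   genes count as singleton families.
#' @param cfg a [phas_config()].
#' @return data.frame `phasirna`, `target_id`, `target_gene`, `score`,
#'   `cleavage_pos`, `orientation`, `relation`
#'   (cis/same_family/trans), `stringent`.
#' @export
predict_targets <- function(phasirnas, transcripts, families = NULL,
                            cfg = phas_config()) {
  out <- list()
  gene_of <- transcripts$gene_id %||% transcripts$id
  for (i in seq_len(nrow(phasirnas))) {
    s <- phasirnas$seq[i]
    for (j in seq_len(nrow(transcripts))) {
      for (orient in c("sense", "antisense")) {
        tgt <- if (orient == "sense") transcripts$seq[j] else
          revcomp(transcripts$seq[j])
        h <- duplex_hits(s, tgt, cfg$target_score_cutoff)
        if (nrow(h) == 0L) next
        out[[length(out) + 1L]] <- data.frame(
          phasirna = s, target_id = transcripts$id[j],
          target_gene = gene_of[j], score = h$score,
          cleavage_pos = h$cleavage, orientation = orient,
          origin_gene = phasirnas$origin_gene[i] %||% NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(phasirna = character(0), target_id = character(0),
                      target_gene = character(0), score = numeric(0),
                      cleavage_pos = integer(0), orientation = character(0),
                      relation = character(0), stringent = logical(0)))
  res <- do.call(rbind, out)
  res$relation <- classify_target(res$target_gene, res$origin_gene, families)
  res$stringent <- res$score <= cfg$stringent_target_cutoff
  res$origin_gene <- NULL
  rownames(res) <- NULL
  res
}

#' Relation of a predicted target to the phasiRNA's origin
#'
#' @param target_gene gene id(s) of the predicted target.
#' @param origin_gene gene id(s) the phasiRNA derives from (NA allowed).
#' @param families named character vector gene_id -> family id; genes
#'   missing from the map are singleton families.
#' @return "cis" (target is the originating gene), "same_family"
#'   (a paralog of it) or "trans".
#' @export
classify_target <- function(target_gene, origin_gene, families = NULL) {
  fam <- function(g) {
    f <- if (!is.null(families)) unname(families[g]) else NA_character_
    ifelse(is.na(f), g, f)
  }
  ifelse(!is.na(origin_gene) & target_gene == origin_gene, "cis",
         ifelse(!is.na(origin_gene) & fam(target_gene) == fam(origin_gene),
                "same_family", "trans"))
}

#' Degradome support for a predicted cleavage site
#'
#' @param ref_id transcript/reference id of the site.
#' @param cleavage_pos 0-based cleavage coordinate.
#' @param degradome_ends data.frame `ref_id`, `pos` (0-based 5'-end
#'   coordinate), `count`; NULL when no degradome library is loaded.
#' @param cfg a [phas_config()] (supplies `min_degradome_reads`).
#' @return "validated", "unsupported" or "no_data".
#' @export
degradome_support <- function(ref_id, cleavage_pos, degradome_ends,
                              cfg = phas_config()) {
  if (is.null(degradome_ends)) return(rep("no_data", length(cleavage_pos)))
  vapply(seq_along(cleavage_pos), function(i) {
    sel <- degradome_ends$ref_id == ref_id[i] &
      abs(degradome_ends$pos - cleavage_pos[i]) <= 1L
    if (sum(degradome_ends$count[sel]) >= cfg$min_degradome_reads)
      "validated" else "unsupported"
  }, character(1L))
}
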