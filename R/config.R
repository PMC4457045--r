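#' Pipeline run configuration
#'
#' Collects every threshold the PHAS discovery pipeline applies, with the
#' defaults used throughout: a nine-cycle sliding window (189 nt at a
#' 21-nt register, stepping 63 nt), at least 10 unique reads per window of
#' which more than half are register length and at least 3 fall in phase,
#' a strict P < 0.001 call for 21-nt loci, a phasing-score cutoff of 15
#' for 24-nt loci, exact mapping with at most 6 genomic hits, 200-nt
#' trigger search flanks with alignment score cutoff 4, target score
#' cutoff 3 (stringent 1.5), a 10 RPM abundance floor for triggers and
#' phasiRNAs, and a 5-fold rule for differential phasiRNA production.
#'
#' @param register_len phase register length in nt, 21 or 24.
#' @param cycles_per_window number of register cycles per window (m).
#' @param window_step window step in nt; default 3 registers.
#' @param min_unique_reads minimum unique reads of any length per window.
#' @param min_inphase_unique minimum unique register-length reads in the
#'   maximal phase register.
#' @param pvalue_cutoff strict upper bound for a positive 21-nt window.
#' @param score_cutoff_24nt minimum phasing score for a positive 24-nt
#'   window.
#' @param max_hits maximum genomic placements per read.
#' @param trigger_flank nt scanned on each side of a locus for triggers.
#' @param trigger_score_cutoff maximum duplex penalty for a trigger.
#' @param target_score_cutoff maximum duplex penalty for a target.
#' @param stringent_target_cutoff stringent target penalty threshold.
#' @param min_rpm abundance floor (reads per million) for trigger and
#'   phasiRNA pools.
#' @param fold_change_cutoff ratio beyond which differential production is
#'   called induced/suppressed.
#' @param min_len,max_len length bounds retained after adaptor trimming.
#' @param rpm_pseudocount pseudocount (RPM) used in differential ratios.
#' @param low_cov,high_cov RNA-seq mean-coverage thresholds (reads/nt)
#'   separating bona fide from retained introns.
#' @param min_degradome_reads degradome 5' ends required at a cleavage
#'   site (+/- 1 nt) for validation.
#' @param rng_seed integer seed recorded in the run manifest.
#' @return an object of class `phas_config` (a named list).
#' @export
phas_config <- function(register_len = 21L,
                        cycles_per_window = 9L,
                        window_step = 3L * register_len,
                        min_unique_reads = 10L,
                        min_inphase_unique = 3L,
                        pvalue_cutoff = 0.001,
                        score_cutoff_24nt = 15,
                        max_hits = 6L,
                        trigger_flank = 200L,
                        trigger_score_cutoff = 4,
                        target_score_cutoff = 3,
                        stringent_target_cutoff = 1.5,
                        min_rpm = 10,
                        fold_change_cutoff = 5,
                        min_len = 18L,
                        max_len = 34L,
                        rpm_pseudocount = 0.1,
                        low_cov = 1,
                        high_cov = 5,
                        min_degradome_reads = 2L,
                        rng_seed = 1L) {
  cfg <- list(
    register_len = as.integer(register_len),
    cycles_per_window = as.integer(cycles_per_window),
    window_step = as.integer(window_step),
    min_unique_reads = as.integer(min_unique_reads),
    min_inphase_unique = as.integer(min_inphase_unique),
    pvalue_cutoff = pvalue_cutoff,
    score_cutoff_24nt = score_cutoff_24nt,
    max_hits = as.integer(max_hits),
    trigger_flank = as.integer(trigger_flank),
    trigger_score_cutoff = trigger_score_cutoff,
    target_score_cutoff = target_score_cutoff,
    stringent_target_cutoff = stringent_target_cutoff,
    min_rpm = min_rpm,
    fold_change_cutoff = fold_change_cutoff,
    min_len = as.integer(min_len),
    max_len = as.integer(max_len),
    rpm_pseudocount = rpm_pseudocount,
    low_cov = low_cov,
    high_cov = high_cov,
    min_degradome_reads = as.integer(min_degradome_reads),
    rng_seed = as.integer(rng_seed)
  )
  validate_phas_config(cfg)
  structure(cfg, class = "phas_config")
}

validate_phas_config <- function(cfg) {
  if (!cfg$register_len %in% c(21L, 24L))
    stop("register_len must be 21 or 24", call. = FALSE)
  counts <- c("cycles_per_window", "window_step", "min_unique_reads",
              "min_inphase_unique", "max_hits", "min_degradome_reads")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop(sprintf("%s must be a count >= 1", f), call. = FALSE)
  if (!(cfg$pvalue_cutoff > 0 && cfg$pvalue_cutoff < 1))
    stop("pvalue_cutoff must lie in (0, 1)", call. = FALSE)
  if (cfg$min_len > cfg$max_len)
    stop("min_len must not exceed max_len", call. = FALSE)
  invisible(cfg)
}

#' Window span implied by a configuration
#' @param cfg a `phas_config`.
#' @return span in nt (`register_len * cycles_per_window`).
#' @export
window_span <- function(cfg) cfg$register_len * cfg$cycles_per_window

#' @export
print.phas_config <- function(x, ...) {
  cat(sprintf("PHAS run configuration (%d-nt register, %d-cycle window = %d nt, step %d nt)\n",
              x$register_len, x$cycles_per_window, window_span(x), x$window_step))
  cat(sprintf("  window filter : >= %d unique reads, > half register-length, >= %d in phase\n",
              x$min_unique_reads, x$min_inphase_unique))
  cat(sprintf("  locus call    : P < %g (21 nt) / phasing score >= %g (24 nt)\n",
              x$pvalue_cutoff, x$score_cutoff_24nt))
  cat(sprintf("  mapping       : exact, <= %d hits; trigger flank %d nt, score <= %g;\n",
              x$max_hits, x$trigger_flank, x$trigger_score_cutoff))
  cat(sprintf("  targets       : score <= %g (stringent %g); pools >= %g RPM; %g-fold rule\n",
              x$target_score_cutoff, x$stringent_target_cutoff, x$min_rpm,
              x$fold_change_cutoff))
  invisible(x)
}
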