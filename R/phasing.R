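# Phase-register assignment, window scanning, the hypergeometric phasing
# P-value, the phasing score, and locus calling.

#' Phase coordinate of an alignment
#'
#' Plus-strand reads keep their leftmost coordinate; minus-strand reads
#' get a +2 offset so that the partner of a perfect siRNA duplex with a
#' 2-nt 3' overhang falls into the same register as its sense strand.
#'
#' @param start 0-based leftmost coordinate(s).
#' @param strand "+" or "-" (vectorised).
#' @param register_len register length (unused by the offset itself;
#'   kept for interface symmetry with the register arithmetic).
#' @return integer phase coordinate(s).
#' @export
register_position <- function(start, strand, register_len = 21L) {
  as.integer(start) + ifelse(strand == "-", 2L, 0L)
}

#' Hypergeometric phasing P-value
#'
#' Probability of observing at least `k` of `n` unique register-length
#' reads in one phase register of a window holding `m` cycles, when
#' reads land uniformly on the `register_len * m` window positions of
#' which `m` are in phase:
#' \deqn{p(k) = \sum_{X=k}^{\min(n,m)}
#'   \frac{\binom{(R-1)m}{n-X}\binom{m}{X}}{\binom{Rm}{n}}}
#' with `R = register_len`. Computed by direct log-binomial summation.
#'
#' @param n unique register-length reads in the window.
#' @param k unique reads in the maximal phase register.
#' @param m cycles per window (phase positions in register).
#' @param register_len register length R (21 or 24).
#' @return P-value in (0, 1].
#' @export
phas_pvalue <- function(n, k, m, register_len = 21L) {
  stopifnot(length(n) == 1L, length(k) == 1L, length(m) == 1L)
  R <- as.integer(register_len)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  if (k < 0L || k > min(n, m))
    stop("k must satisfy 0 <= k <= min(n, m)", call. = FALSE)
  if (n > R * m) stop("n cannot exceed register_len * m", call. = FALSE)
  X <- k:min(n, m)
  X <- X[n - X <= (R - 1L) * m]
  lt <- lchoose((R - 1L) * m, n - X) + lchoose(m, X) - lchoose(R * m, n)
  min(1, sum(exp(lt)))
}

#' Phasing score
#'
#' Log-scale statistic rewarding in-phase read abundance spread over
#' occupied registers:
#' \deqn{score = (occ - 2)\,\ln\!\left(1 + 10\frac{\sum P}{1 + \sum U}\right)}
#' where `occ` is the number of the window's cycle positions (of the
#' chosen phase) holding at least one unique register-length read,
#' `sum_p` the total in-phase read count and `sum_u` the number of
#' unique register-length reads out of phase. Zero when fewer than three
#' registers are occupied.
#'
#' @param sum_p total in-phase abundance (reads).
#' @param sum_u unique out-of-phase register-length reads.
#' @param occupied occupied in-phase cycle positions (0..m).
#' @return non-negative score.
#' @export
phasing_score <- function(sum_p, sum_u, occupied) {
  stopifnot(sum_p >= 0, sum_u >= 0, occupied >= 0)
  if (occupied < 3L) return(0)
  (occupied - 2) * log1p(10 * sum_p / (1 + sum_u))
}

#' Window-level candidate filter
#'
#' A window passes iff it holds at least `min_unique_reads` unique reads
#' of any length, strictly more than half of them are register length,
#' and at least `min_inphase_unique` unique register-length reads fall
#' in the maximal phase register.
#'
#' @param windows window data.frame from [scan_windows()].
#' @param cfg a [phas_config()].
#' @return `windows` with logical `pass` and character `fail_reason`
#'   columns filled.
#' @export
window_filter <- function(windows, cfg) {
  reason <- rep(NA_character_, nrow(windows))
  reason[windows$k_inphase < cfg$min_inphase_unique] <- "inphase<min"
  reason[!(windows$n_unique_reg > windows$n_unique_all / 2)] <- "register-length<=half"
  reason[windows$n_unique_all < cfg$min_unique_reads] <- "unique<min"
  windows$pass <- is.na(reason)
  windows$fail_reason <- reason
  windows
}

#' Window start positions along a reference
#'
#' @param ref_len reference length in nt.
#' @param cfg a [phas_config()].
#' @return integer vector of 0-based window starts (every start `s` with
#'   `s + span <= ref_len`, on the `window_step` grid).
#' @export
window_starts <- function(ref_len, cfg) {
  span <- window_span(cfg)
  if (ref_len < span) return(integer(0))
  seq.int(0L, ref_len - span, by = cfg$window_step)
}

#' Scan references with a phased sliding window
#'
#' Windows of `register_len * cycles_per_window` nt (189 nt in 21-nt
#' mode) are placed every `window_step` nt (63 nt) along each reference.
#' Within a window every alignment is assigned a phase coordinate
#' ([register_position()]); for each of the `register_len` candidate
#' phase offsets the number of unique register-length reads in that
#' register is tallied and the offset maximising it is chosen (ties to
#' the smallest offset). The hypergeometric P-value and phasing score
#' are computed for windows passing [window_filter()].
#'
#' @param alignments alignment data.frame ([map_reads()] /
#'   [import_alignments()]).
#' @param ref_lengths named integer vector of reference lengths.
#' @param cfg a [phas_config()].
#' @return data.frame with one row per window that contains at least one
#'   alignment: tallies, chosen `phase_offset` (register index within
#'   the window), `abs_phase` (genomic residue class), `pvalue`,
#'   `phasing_score`, `pass`, `fail_reason`.
#' @export
scan_windows <- function(alignments, ref_lengths, cfg) {
  R <- cfg$register_len
  m <- cfg$cycles_per_window
  span <- window_span(cfg)
  step <- cfg$window_step
  empty <- data.frame(ref_id = character(0), start = integer(0),
                      phase_offset = integer(0), abs_phase = integer(0),
                      n_unique_all = integer(0), n_unique_reg = integer(0),
                      k_inphase = integer(0), occupied = integer(0),
                      inphase_abundance = numeric(0),
                      outphase_unique = integer(0), pvalue = numeric(0),
                      phasing_score = numeric(0), pass = logical(0),
                      fail_reason = character(0))
  if (nrow(alignments) == 0L) return(empty)
  al <- data.table::as.data.table(alignments)
  al[, phase_pos := register_position(start, strand, R)]
  # replicate each alignment into every window covering its phase position
  reps <- span %/% step
  al_rep <- al[rep(seq_len(.N), each = reps)]
  al_rep[, w := (rep(0:(reps - 1L), length.out = .N))]
  al_rep[, w := (phase_pos %/% step - w) * step]
  maxw <- ref_lengths[al_rep$ref_id] - span
  al_rep <- al_rep[w >= 0L & w <= maxw & phase_pos >= w & phase_pos < w + span]
  if (nrow(al_rep) == 0L) return(empty)
  al_rep[, read_key := paste(seq, strand, start, sep = "|")]
  al_rep[, is_reg := length == R]
  al_rep[, register := (phase_pos - w) %% R]

  per_win <- al_rep[, {
    reg <- .SD[is_reg == TRUE]
    n_all <- data.table::uniqueN(read_key)
    n_reg <- data.table::uniqueN(reg$read_key)
    if (nrow(reg) > 0L) {
      by_reg <- reg[, .(k = data.table::uniqueN(read_key),
                        abund = sum(count)), by = register]
      data.table::setorder(by_reg, -k, register)
      off <- by_reg$register[1L]
      k <- by_reg$k[1L]
      inph <- reg[register == off]
      occ <- data.table::uniqueN(inph$phase_pos)
      sum_p <- sum(inph$count)
      sum_u <- n_reg - k
    } else {
      off <- 0L; k <- 0L; occ <- 0L; sum_p <- 0; sum_u <- 0L
    }
    .(phase_offset = as.integer(off), n_unique_all = n_all,
      n_unique_reg = n_reg, k_inphase = as.integer(k),
      occupied = as.integer(occ), inphase_abundance = as.numeric(sum_p),
      outphase_unique = as.integer(sum_u))
  }, by = .(ref_id, w)]
  data.table::setnames(per_win, "w", "start")
  per_win[, abs_phase := (start + phase_offset) %% R]
  out <- as.data.frame(per_win)
  out <- window_filter(out, cfg)
  out$pvalue <- NA_real_
  out$phasing_score <- NA_real_
  for (i in which(out$pass)) {
    # reads land on R*m window positions; clamp n and k to the model's
    # support (two strands can in principle stack distinct reads beyond it)
    n_eff <- min(out$n_unique_reg[i], R * m)
    k_eff <- min(out$k_inphase[i], m, n_eff)
    out$pvalue[i] <- phas_pvalue(n_eff, k_eff, m, R)
    out$phasing_score[i] <- phasing_score(out$inphase_abundance[i],
                                          out$outphase_unique[i],
                                          out$occupied[i])
  }
  out[order(out$ref_id, out$start), ]
}

#' Merge positive windows into PHAS loci
#'
#' Adjacent or overlapping positive windows on the same reference whose
#' start difference is a multiple of the register length and whose
#' chosen phase offsets agree (same genomic residue class) are chained
#' into one locus, which keeps the union extent, the minimum P-value,
#' the maximum phasing score and the window count.
#'
#' @param positives positive windows (rows of [scan_windows()] output).
#' @param cfg a [phas_config()].
#' @return locus data.frame (no member-read bookkeeping; see
#'   [call_phas_loci()]).
#' @export
merge_windows <- function(positives, cfg) {
  span <- window_span(cfg)
  R <- cfg$register_len
  empty <- data.frame(locus_id = character(0), ref_id = character(0),
                      start = integer(0), end = integer(0),
                      register_len = integer(0), phase_offset = integer(0),
                      best_pvalue = numeric(0), best_score = numeric(0),
                      window_count = integer(0))
  if (nrow(positives) == 0L) return(empty)
  p <- positives[order(positives$ref_id, positives$start), , drop = FALSE]
  key <- paste(p$ref_id, p$abs_phase)
  out <- list()
  for (kk in unique(key)) {
    sub <- p[key == kk, , drop = FALSE]
    brk <- c(TRUE, diff(sub$start) > span | diff(sub$start) %% R != 0L)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      s <- sub[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        ref_id = s$ref_id[1L], start = min(s$start),
        end = max(s$start) + span, register_len = R,
        phase_offset = s$abs_phase[1L],
        best_pvalue = suppressWarnings(min(s$pvalue, na.rm = TRUE)),
        best_score = suppressWarnings(max(s$phasing_score, na.rm = TRUE)),
        window_count = nrow(s), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$best_score[!is.finite(res$best_score)] <- NA_real_
  res$best_pvalue[!is.finite(res$best_pvalue)] <- NA_real_
  res$locus_id <- sprintf("%s:%d-%d:%dnt", res$ref_id, res$start, res$end,
                          res$register_len)
  res <- res[order(res$ref_id, res$start),
             c("locus_id", "ref_id", "start", "end", "register_len",
               "phase_offset", "best_pvalue", "best_score", "window_count")]
  rownames(res) <- NULL
  res
}

#' Call PHAS loci from scanned windows
#'
#' In 21-nt mode a window is positive iff its P-value is strictly below
#' `pvalue_cutoff`; in 24-nt mode iff its phasing score is at least
#' `score_cutoff_24nt`. Positive windows are merged by
#' [merge_windows()]; each locus then collects its member reads (the
#' register-length alignments whose phase coordinate lies in the locus
#' and matches its residue class) and their total abundance.
#'
#' @param windows output of [scan_windows()].
#' @param alignments the alignments the windows were scanned from.
#' @param cfg a [phas_config()].
#' @param library_total cleaned library size for RPM (optional).
#' @return locus data.frame with columns of [merge_windows()] plus
#'   `total_count`, `total_rpm` and attribute `member_reads` (data.frame
#'   keyed by `locus_id`).
#' @export
call_phas_loci <- function(windows, alignments, cfg, library_total = NULL) {
  if (nrow(windows) == 0L) {
    loci <- merge_windows(windows, cfg)
  } else {
    positive <- windows$pass &
      (if (cfg$register_len == 21L) !is.na(windows$pvalue) &
         windows$pvalue < cfg$pvalue_cutoff
       else !is.na(windows$phasing_score) &
         windows$phasing_score >= cfg$score_cutoff_24nt)
    loci <- merge_windows(windows[positive, , drop = FALSE], cfg)
  }
  members <- list()
  loci$total_count <- rep(0, nrow(loci))
  if (nrow(loci) > 0L && nrow(alignments) > 0L) {
    ph <- register_position(alignments$start, alignments$strand,
                            cfg$register_len)
    for (i in seq_len(nrow(loci))) {
      inl <- alignments$ref_id == loci$ref_id[i] &
        alignments$length == cfg$register_len &
        ph >= loci$start[i] & ph < loci$end[i] &
        (ph %% cfg$register_len) == loci$phase_offset[i]
      mr <- alignments[inl, , drop = FALSE]
      if (nrow(mr) > 0L) {
        mr$locus_id <- loci$locus_id[i]
        members[[length(members) + 1L]] <- mr
        loci$total_count[i] <- sum(mr$count)
      }
    }
  }
  loci$total_rpm <- if (!is.null(library_total) && library_total > 0)
    compute_rpm(loci$total_count, library_total) else rep(NA_real_, nrow(loci))
  member_df <- if (length(members) > 0L) do.call(rbind, members) else
    cbind(alignments[0, , drop = FALSE], locus_id = character(0))
  rownames(member_df) <- NULL
  structure(loci, member_reads = member_df)
}
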