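test_that("phase coordinates apply the +2 antisense duplex offset", {
  expect_equal(register_position(0, "+"), 0L)
  expect_equal(register_position(19, "-"), 21L)  # duplex partner register 0
  expect_equal(register_position(c(44, 44), c("+", "-")), c(44L, 46L))
  # register arithmetic within a window starting at 2
  expect_equal((44 - 2) %% 21, 0)
})

test_that("phasing P-value matches the exact-rational oracle on a spot grid", {
  # frozen exact value: p(n=3, k=3, m=9) = C(9,3)/C(189,3) = 84/1107414
  expect_equal(phas_pvalue(3, 3, 9), 84 / 1107414, tolerance = 1e-12)
  grid <- expand.grid(n = c(3, 5, 12, 25, 40), k = 0:5, m = c(3, 6, 9))
  grid <- grid[grid$k <= pmin(grid$n, grid$m), ]
  grid$R <- 21
  exact <- exact_pvalue_oracle(grid)
  got <- mapply(phas_pvalue, grid$n, grid$k, grid$m)
  expect_true(all(abs(got - exact) <= 1e-9 * pmax(exact, 1e-300)))
  # second, library-based cross-check: upper hypergeometric tail
  ph <- mapply(function(n, k, m) stats::phyper(k - 1, m, 20 * m, n,
                                               lower.tail = FALSE),
               grid$n, grid$k, grid$m)
  expect_equal(got, ph, tolerance = 1e-9)
})

test_that("phasing P-value is a proper tail: monotone in k and normalised", {
  for (m in c(3, 6, 9)) for (n in c(4, 10, 25)) {
    ks <- 0:min(n, m)
    p <- vapply(ks, function(k) phas_pvalue(n, k, m), numeric(1))
    expect_true(all(diff(p) <= 1e-12))       # non-increasing in k
    expect_equal(p[1], 1, tolerance = 1e-12) # tail from 0 is everything
    pmf <- vapply(ks, function(x)
      exp(lchoose(20 * m, n - x) + lchoose(m, x) - lchoose(21 * m, n)),
      numeric(1))
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
  }
  expect_error(phas_pvalue(5, 6, 9), "k must")
})

test_that("phasing score follows its closed form and degenerate zeros", {
  expect_equal(phasing_score(50, 4, 5), 3 * log(101))
  expect_equal(phasing_score(100, 0, 2), 0)  # exponent occ - 2 = 0
  expect_equal(phasing_score(0, 7, 8), 0)    # no in-phase abundance
  expect_equal(phasing_score(10, 2, 1), 0)   # under-occupied
  expect_gt(phasing_score(1, 0, 9), 0)
})

test_that("window placement enumerates every on-grid start that fits", {
  cfg <- phas_config()
  expect_equal(window_starts(400, cfg), c(0L, 63L, 126L, 189L))
  expect_equal(window_starts(188, cfg), integer(0))
  cfg24 <- phas_config(register_len = 24)
  expect_equal(window_span(cfg24), 216L)
  expect_equal(window_starts(300, cfg24), c(0L, 72L))
})

test_that("window scan picks the offset maximising unique in-phase reads", {
  g <- tiny_genome(2000, seed = 21)
  cfg <- phas_config()
  # 10 distinct sense 21-mers at positions congruent 5 mod 21 inside window 0
  al <- data.frame(seq = vapply(0:9, function(i)
                     substr(g[[1]], 5 + i * 21 + 1, 5 + i * 21 + 21), ""),
                   count = 4L, length = 21L, ref_id = "chr1", strand = "+",
                   start = 5 + (0:9) * 21, hits = 1L)
  w <- scan_windows(al, c(chr1 = 2000L), cfg)
  w0 <- w[w$start == 0, ]
  expect_equal(w0$phase_offset, 5L)
  expect_equal(w0$k_inphase, 9L)  # 9 of the 10 cycles fit in window [0,189)
  expect_equal(w0$occupied, 9L)
  expect_equal(scan_windows(al[0, ], c(chr1 = 2000L), cfg),
               scan_windows(al[0, ], c(chr1 = 2000L), cfg)) # empty in, empty out
  expect_equal(nrow(scan_windows(al[0, ], c(chr1 = 2000L), cfg)), 0L)
})

test_that("window filter enforces the three candidate thresholds", {
  cfg <- phas_config()
  w <- data.frame(n_unique_all = c(9, 10, 10, 10),
                  n_unique_reg = c(9, 5, 6, 6),
                  k_inphase = c(5, 5, 2, 3))
  out <- window_filter(w, cfg)
  expect_equal(out$pass, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(out$fail_reason[1], "unique<min")
  expect_equal(out$fail_reason[2], "register-length<=half") # exactly half fails
  expect_equal(out$fail_reason[3], "inphase<min")
})

test_that("locus calling applies strict P < 0.001 and score >= 15 boundaries", {
  cfg <- phas_config()
  win <- data.frame(ref_id = "chr1", start = 0L, phase_offset = 0L,
                    abs_phase = 0L, n_unique_all = 12L, n_unique_reg = 12L,
                    k_inphase = 5L, occupied = 5L, inphase_abundance = 50,
                    outphase_unique = 7L, pvalue = 0.001,
                    phasing_score = 10, pass = TRUE,
                    fail_reason = NA_character_)
  none <- call_phas_loci(win, win[0, c()], cfg)
  expect_equal(nrow(none), 0L)   # p exactly 0.001 is not positive
  win$pvalue <- 0.000999
  one <- call_phas_loci(win, data.frame(seq = character(0),
                                        count = integer(0),
                                        length = integer(0),
                                        ref_id = character(0),
                                        strand = character(0),
                                        start = integer(0)), cfg)
  expect_equal(nrow(one), 1L)

  cfg24 <- phas_config(register_len = 24)
  win24 <- win; win24$pvalue <- 0.5; win24$phasing_score <- 15
  expect_equal(nrow(call_phas_loci(win24, win[0, c()], cfg24)), 1L) # >= 15 positive
  win24$phasing_score <- 14.999
  expect_equal(nrow(call_phas_loci(win24, win[0, c()], cfg24)), 0L)
})

test_that("windows merge only when adjacent in the same phase register", {
  cfg <- phas_config()
  base <- data.frame(ref_id = "chr1", phase_offset = 0L,
                     n_unique_all = 12L, n_unique_reg = 12L, k_inphase = 6L,
                     occupied = 6L, inphase_abundance = 50,
                     outphase_unique = 2L, pvalue = 1e-6,
                     phasing_score = 20, pass = TRUE,
                     fail_reason = NA_character_)
  two <- rbind(cbind(base, start = 0L), cbind(base, start = 63L))
  two$abs_phase <- (two$start + two$phase_offset) %% 21L
  # same residue 63 = 3*21 apart: one locus [0, 252)
  two$abs_phase <- 0L
  m1 <- merge_windows(two, cfg)
  expect_equal(nrow(m1), 1L)
  expect_equal(c(m1$start, m1$end), c(0L, 252L))
  # offset residues differing: two loci
  two2 <- two; two2$abs_phase <- c(0L, 1L)
  expect_equal(nrow(merge_windows(two2, cfg)), 2L)
  # single window: span-length locus
  m3 <- merge_windows(two[1, ], cfg)
  expect_equal(m3$end - m3$start, 189L)
  # far-apart same-residue windows stay separate
  far <- rbind(cbind(base, start = 0L), cbind(base, start = 630L))
  far$abs_phase <- 0L
  expect_equal(nrow(merge_windows(far, cfg)), 2L)
})

test_that("antisense reads fall entirely into sense registers via the +2 offset", {
  g <- tiny_genome(3000, seed = 5)
  cfg <- phas_config()
  both <- duplex_locus_alignments(g, start = 400, cycles = 10)
  sense <- duplex_locus_alignments(g, start = 400, cycles = 10, strands = "+")
  ws <- scan_windows(sense, c(chr1 = 3000L), cfg)
  wb <- scan_windows(both, c(chr1 = 3000L), cfg)
  for (s in intersect(ws$start, wb$start)) {
    a <- ws[ws$start == s, ]; b <- wb[wb$start == s, ]
    expect_equal(b$phase_offset, a$phase_offset)
    # in-phase fraction 1 in both: zero out-of-phase uniques
    expect_equal(a$outphase_unique, 0L)
    expect_equal(b$outphase_unique, 0L)
    expect_equal(b$n_unique_reg, 2L * a$n_unique_reg)
  }
})

test_that("locus detection is translation-invariant", {
  # shifting by a whole window step relocates everything exactly; for a
  # one-register shift the window grid samples different frames, so the
  # guarantee is at detection level: the locus is still called, in the
  # shifted residue class, covering the shifted phased reads
  g <- tiny_genome(3000, seed = 9)
  cfg <- phas_config()
  al <- duplex_locus_alignments(g, start = 500, cycles = 10)
  l1 <- call_phas_loci(scan_windows(al, c(chr1 = 3000L), cfg), al, cfg)
  expect_equal(nrow(l1), 1L)

  al63 <- al; al63$start <- al63$start + 63L
  l63 <- call_phas_loci(scan_windows(al63, c(chr1 = 3063L), cfg), al63, cfg)
  expect_equal(l63$start, l1$start + 63L)
  expect_equal(l63$end, l1$end + 63L)
  expect_equal(l63$best_pvalue, l1$best_pvalue)

  al21 <- al; al21$start <- al21$start + 21L
  l21 <- call_phas_loci(scan_windows(al21, c(chr1 = 3021L), cfg), al21, cfg)
  expect_equal(nrow(l21), 1L)
  expect_equal(l21$phase_offset, (l1$phase_offset + 21L) %% 21L)
  expect_lte(l21$start, 521L)  # covers the shifted phased reads
  expect_gte(l21$end, 521L + 210L)
  expect_lte(l21$best_pvalue, cfg$pvalue_cutoff)
})
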