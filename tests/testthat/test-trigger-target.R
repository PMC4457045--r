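test_that("duplex scoring reproduces hand-scored examples", {
  set.seed(31)
  site <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                collapse = "")
  srna <- revcomp(site)
  target <- paste0("AAAAA", site, "CCCCC")
  best <- align_srna_target(srna, target)
  expect_equal(best$score, 0)
  expect_equal(best$t_start, 5L)
  # cleavage opposite sRNA position 10: site base 21 - 10 = index 11 of site
  expect_equal(best$cleavage, 5L + 21L - 10L)

  # single G:U at sRNA position 15 (outside 2-13): 0.5
  s <- strsplit(srna, "")[[1]]
  t2 <- strsplit(site, "")[[1]]
  # sRNA pos 15 pairs target index 21 - 15 = 6 (0-based within site)
  s[15] <- "G"; t2[7] <- "T" # force G:T wobble (overwrite both sides)
  sc <- align_srna_target(paste(s, collapse = ""),
                          paste(t2, collapse = ""))
  expect_equal(sc$score, 0.5)

  # single mismatch at sRNA position 5: doubled to 2.0
  s <- strsplit(srna, "")[[1]]
  t3 <- strsplit(site, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bad <- setdiff(c("A", "C", "G", "T"),
                 c(comp[s[5]], ifelse(s[5] == "G", "T", ""),
                   ifelse(s[5] == "T", "G", "")))
  t3[21 - 5 + 1] <- bad[1]
  sc2 <- align_srna_target(paste(s, collapse = ""),
                           paste(t3, collapse = ""))
  expect_equal(sc2$score, 2)

  # window shorter than the sRNA: no alignment
  expect_equal(nrow(align_srna_target(srna, "ACGTACGT")), 0L)
})

test_that("duplex scoring equals exhaustive enumeration on random cases", {
  set.seed(41)
  for (rep in 1:12) {
    L <- sample(20:22, 1)
    srna <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = "")
    tlen <- sample(30:55, 1)
    target <- paste(sample(c("A", "C", "G", "T"), tlen, replace = TRUE),
                    collapse = "")
    if (rep %% 3 == 0) { # plant a degraded complement so scores are small
      site <- revcomp(srna)
      ch <- strsplit(site, "")[[1]]
      i <- sample(L, 1); ch[i] <- sample(c("A", "C", "G", "T"), 1)
      target <- paste0(substr(target, 1, 5), paste(ch, collapse = ""),
                       substr(target, 6 + 0, tlen - L))
    }
    oracle <- naive_duplex_min(srna, target)
    got <- align_srna_target(srna, target)
    expect_equal(got$score, oracle)
  }
})

test_that("structural duplex score is symmetric under joint reverse complementation", {
  # the positional 2-13 doubling and the G:U discount are defined from
  # the sRNA 5' end, so the full plant score is intentionally
  # orientation-specific; the underlying duplex structure (uniform
  # penalties, wobble = mismatch) must be strand-symmetric
  set.seed(51)
  for (rep in 1:6) {
    srna <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                  collapse = "")
    target <- paste(sample(c("A", "C", "G", "T"), 45, replace = TRUE),
                    collapse = "")
    a <- align_srna_target(srna, target, weighted = FALSE, wobble = 1)
    b <- align_srna_target(revcomp(srna), revcomp(target),
                           weighted = FALSE, wobble = 1)
    expect_equal(a$score, b$score)
  }
  # and a perfect duplex stays perfect with the full plant scoring
  site <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                collapse = "")
  tgt <- paste0("GGGGG", site, "AAAAA")
  expect_equal(align_srna_target(revcomp(site), tgt)$score, 0)
  expect_equal(align_srna_target(site, revcomp(tgt))$score, 0)
})

test_that("phase consistency is residue arithmetic modulo the register", {
  locus <- data.frame(phase_offset = 5L, register_len = 21L)
  expect_equal(phase_consistency(5L, locus), "in_phase")
  expect_equal(phase_consistency(15L, locus), "out_of_phase")
  expect_equal(phase_consistency(5L - 42L, locus), "in_phase") # 2 registers upstream
  expect_equal(phase_consistency(5L + 63L, locus), "in_phase")
})

test_that("trigger search recovers a planted trigger and honours thresholds", {
  g <- tiny_genome(3000, seed = 61)
  cfg <- phas_config()
  c0 <- 1000L
  srna <- revcomp(substr(g[[1]], c0 - 12 + 1, c0 + 10)) # 22-nt, cleaves at c0
  locus <- data.frame(locus_id = "L", ref_id = "chr1", start = c0,
                      end = c0 + 210L, register_len = 21L,
                      phase_offset = c0 %% 21L)
  pool <- data.frame(seq = srna, count = 60L, rpm = 50)
  tr <- find_triggers(locus, pool, g, cfg)
  expect_gte(nrow(tr), 1L)
  hit <- tr[tr$cleavage_pos == c0, ]
  expect_equal(hit$score, 0)
  expect_equal(hit$end, "5prime")
  expect_equal(hit$phase_relation, "in_phase")
  expect_equal(hit$trigger_len, 22L)
})

test_that("out-of-phase triggers survive only as confirmed known miRNAs", {
  cands <- data.frame(locus_id = "L", seq = c("a", "b", "c", "d"),
                      trigger_len = 21L, rpm = 50, end = "5prime",
                      score = 1, cleavage_pos = 0L,
                      phase_relation = c("in_phase", rep("out_of_phase", 3)),
                      mirna_status = c("putative", "putative", "known", "known"),
                      degradome = c("no_data", "validated", "no_data",
                                    "validated"),
                      whitelisted = c(FALSE, FALSE, FALSE, FALSE))
  kept <- filter_triggers(cands)
  expect_equal(kept$seq, c("a", "d"))
  cands$whitelisted[3] <- TRUE
  expect_equal(filter_triggers(cands)$seq, c("a", "c", "d"))
})

test_that("trigger models follow the two-hit / one-hit classification", {
  row <- function(len, pos) data.frame(trigger_len = len, cleavage_pos = pos)
  expect_equal(classify_trigger_model(rbind(row(21, 0), row(21, 210))),
               "two_hit")
  expect_equal(classify_trigger_model(row(22, 0)), "one_hit_22")
  expect_equal(classify_trigger_model(row(21, 0)), "unclassified")
  expect_equal(classify_trigger_model(row(21, 0)[0, ]), "none")
})

test_that("miRNA annotation tolerates two mismatches and one-off lengths", {
  known <- data.frame(id = "miR1", seq = "TTGACAGAAGATAGAGAGCAC")
  expect_equal(annotate_mirna("TTGACAGAAGATAGAGAGCAC", known), "known")
  two <- "TAGACAGAAGATAGAGAGCAA"
  expect_equal(annotate_mirna(two, known), "known")
  three <- "TAGTCAGAAGATAGAGAGCAA"
  expect_equal(annotate_mirna(three, known), "putative")
  short <- substr(known$seq, 1, 20) # length 20, 0 mismatches
  expect_equal(annotate_mirna(short, known), "known")
  expect_equal(annotate_mirna("TTGACAGAAGATAGAGAGCAC", NULL), "putative")
})

test_that("target relations split into cis, same-family and trans", {
  fam <- c(g1 = "famA", g2 = "famA", g3 = "famB")
  expect_equal(classify_target("g1", "g1", fam), "cis")
  expect_equal(classify_target("g2", "g1", fam), "same_family")
  expect_equal(classify_target("g3", "g1", fam), "trans")
  # genes absent from the map are singleton families
  expect_equal(classify_target("gX", "g1", fam), "trans")
  expect_equal(classify_target("gX", "gX", NULL), "cis")
})

test_that("degradome validation needs two 5' ends within one nt", {
  cfg <- phas_config()
  ends <- data.frame(ref_id = "tx1", pos = c(100L, 101L, 200L),
                     count = c(5L, 5L, 1L))
  expect_equal(degradome_support("tx1", 100L, ends, cfg), "validated")
  expect_equal(degradome_support("tx1", 195L, ends, cfg), "unsupported")
  expect_equal(degradome_support("tx1", 100L, NULL, cfg), "no_data")
  expect_equal(degradome_support("tx1", 200L, ends, cfg), "unsupported")
})

test_that("hairpin evaluation recognises a perfect inverted repeat", {
  set.seed(71)
  arm <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
  hp <- paste0(arm, "TTTTTT", revcomp(arm))
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  g <- c(chr1 = paste0(pad(200), hp, pad(200)))
  srna <- substr(arm, 10, 30) # sits in the 5' arm
  st <- 200L + 9L
  v <- evaluate_hairpin(srna, g, data.frame(ref_id = "chr1", strand = "+",
                                            start = st))
  expect_equal(v, "plausible_mirna")
  # homopolymer context folds into nothing
  g2 <- c(chr1 = strrep("A", 500))
  v2 <- evaluate_hairpin(strrep("A", 21), g2,
                         data.frame(ref_id = "chr1", strand = "+",
                                    start = 200L))
  expect_equal(v2, "not_hairpin")
})

test_that("hairpin evaluation degrades to no_engine without the folding tool", {
  res <- withr::with_envvar(c(PATH = tempdir()), {
    evaluate_hairpin("ACGTACGTACGTACGTACGTA",
                     c(chr1 = strrep("ACGT", 200)),
                     data.frame(ref_id = "chr1", strand = "+", start = 100L))
  })
  expect_equal(res, "no_engine")
})
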