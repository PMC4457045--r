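make_test_models <- function() {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1", strand = "+",
                      start = c(0L, 5000L), end = c(1000L, 6000L))
  exons <- data.frame(gene_id = c("gA", "gA", "gB"),
                      tx_id = c("gA.t1", "gA.t1", "gB.t1"),
                      chrom = "chr1", strand = "+",
                      start = c(0L, 600L, 5000L), end = c(300L, 1000L, 6000L))
  gene_models(genes, exons)
}

fake_locus <- function(start, end, members = NULL, id = NULL) {
  id <- id %||% sprintf("chr1:%d-%d:21nt", start, end)
  l <- data.frame(locus_id = id, ref_id = "chr1", start = start, end = end,
                  register_len = 21L, phase_offset = start %% 21L,
                  best_pvalue = 1e-5, best_score = 20, window_count = 1L,
                  total_count = 100, total_rpm = 50,
                  stringsAsFactors = FALSE)
  if (!is.null(members)) attr(l, "member_reads") <- members
  l
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("loci are classified by their phased-read footprint", {
  models <- make_test_models()
  # entirely inside gA's intron [300, 600)
  mem <- data.frame(seq = "x", count = 1L, length = 21L, ref_id = "chr1",
                    strand = "+", start = c(330L, 351L, 372L), hits = 1L,
                    locus_id = "L1")
  li <- classify_locus(fake_locus(309L, 498L, mem, id = "L1"), models)
  expect_equal(li$genomic_class, "intron")
  expect_equal(li$gene_id, "gA")
  # straddling the exon/intron boundary at 300
  mem2 <- mem; mem2$start <- c(280L, 301L, 322L); mem2$locus_id <- "L2"
  lj <- classify_locus(fake_locus(280L, 469L, mem2, id = "L2"), models)
  expect_equal(lj$genomic_class, "exon_intron")
  # far from any gene
  lk <- classify_locus(fake_locus(3000L, 3189L), models)
  expect_equal(lk$genomic_class, "intergenic")
  expect_true(is.na(lk$gene_id))
})

test_that("classification is a partition: every locus gets exactly one class", {
  models <- make_test_models()
  loci <- do.call(rbind, lapply(c(50L, 320L, 2500L, 5100L),
                                function(s) fake_locus(s, s + 189L)))
  out <- classify_locus(loci, models)
  expect_false(any(is.na(out$genomic_class)))
  s <- summarize_loci(out)
  expect_equal(s$total, nrow(loci))
  expect_equal(s$exon + s$intron + s$exon_intron + s$intergenic, s$total)
})

test_that("gene-level merging combines same-gene loci and is idempotent", {
  models <- make_test_models()
  l1 <- fake_locus(10L, 199L); l2 <- fake_locus(700L, 889L)
  l3 <- fake_locus(3000L, 3189L)
  loci <- classify_locus(rbind(l1, l2, l3), models)
  merged <- merge_by_gene(loci)
  expect_equal(nrow(merged), 2L) # gA's two loci combine; intergenic untouched
  gl <- merged[!is.na(merged$gene_id), ]
  expect_equal(c(gl$start, gl$end), c(10L, 889L))
  expect_equal(gl$total_count, 200)
  expect_equal(merge_by_gene(merged), merged) # idempotent
  expect_equal(nrow(merge_by_gene(loci[0, ])), 0L)
})

test_that("intron retention calls follow mean RNA-seq coverage", {
  models <- make_test_models()
  mem <- data.frame(seq = "x", count = 1L, length = 21L, ref_id = "chr1",
                    strand = "+", start = c(330L, 351L), hits = 1L,
                    locus_id = "L1")
  locus <- classify_locus(fake_locus(309L, 498L, mem, id = "L1"), models)
  cfg <- phas_config()
  no_cov <- data.frame(chrom = "chr1", start = 0L, end = 300L, value = 10)
  expect_equal(intron_retention_support(locus, models, no_cov, cfg)$call,
               "bona_fide_intron") # zero coverage over the intron itself
  hi <- data.frame(chrom = "chr1", start = 300L, end = 600L, value = 50)
  expect_equal(intron_retention_support(locus, models, hi, cfg)$call,
               "retained_intron")
  mid <- data.frame(chrom = "chr1", start = 300L, end = 600L, value = 2)
  expect_equal(intron_retention_support(locus, models, mid, cfg)$call,
               "unknown")
  expect_equal(intron_retention_support(locus, models, NULL, cfg)$call,
               "unknown")
})

test_that("differential verdicts follow the 5-fold rule and status changes", {
  cfg <- phas_config()
  la <- rbind(fake_locus(0L, 189L, id = "A"), fake_locus(1000L, 1189L, id = "B"),
              fake_locus(2000L, 2189L, id = "C"))
  la$gene_id <- NA_character_
  la$total_count <- c(100, 100, 100)
  lb <- la
  lb$total_count <- c(13, 600, 100)
  d <- compare_libraries(la, lb, 1e6, 1e6, cfg)
  d <- d[order(d$key), ]
  expect_equal(d$verdict[1], "suppressed") # 100 -> 13 RPM, > 5-fold down
  expect_equal(d$verdict[2], "induced")    # 6-fold up
  expect_equal(d$verdict[3], "stable")
  # antisymmetry: swapping libraries inverts ratios and verdicts
  ds <- compare_libraries(lb, la, 1e6, 1e6, cfg)
  ds <- ds[order(ds$key), ]
  expect_equal(ds$ratio, 1 / d$ratio, tolerance = 1e-12)
  map <- c(induced = "suppressed", suppressed = "induced", stable = "stable")
  expect_equal(unname(map[d$verdict]), ds$verdict)
})

test_that("a locus losing its reads in library B is lost_PHAS", {
  cfg <- phas_config()
  la <- fake_locus(0L, 189L, id = "A")
  la$gene_id <- NA_character_
  lb <- la[0, ]
  # B has residual (non-PHAS) reads at the locus
  aln_b <- data.frame(seq = "x", count = 3L, length = 21L, ref_id = "chr1",
                      strand = "+", start = 21L, hits = 1L)
  d <- compare_libraries(la, lb, 1e6, 1e6, cfg, aln_b = aln_b)
  expect_equal(d$verdict, "lost_PHAS")
  expect_equal(d$status_b, "siRNA_only")
  # and with no reads at all it is silent but still lost
  d2 <- compare_libraries(la, lb, 1e6, 1e6, cfg)
  expect_equal(d2$verdict, "lost_PHAS")
  expect_equal(d2$status_b, "silent")
  # gained in the swap
  d3 <- compare_libraries(lb, la, 1e6, 1e6, cfg)
  expect_equal(d3$verdict, "gained_PHAS")
})
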