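# Smaller-than-default simulations keep the unit suite fast; the default
# study conditions are exercised in the acceptance tests.
small_sim <- function(...) {
  defaults <- list(genome_len = 60000L, n_genes = 8L, n_phas_exonic = 2L,
                   n_phas_intronic = 2L, n_phas_junction = 1L,
                   n_phas_intergenic = 1L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("the generator is byte-identical under a fixed seed", {
  a <- make_library(small_sim(seed = 5L))
  b <- make_library(small_sim(seed = 5L))
  expect_identical(a$genome, b$genome)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  c <- make_library(small_sim(seed = 6L))
  expect_false(identical(a$genome, c$genome))
})

test_that("generator contracts: gene requirements and intron structure", {
  expect_error(make_genome(sim_config(n_genes = 0L, n_phas_exonic = 1L)),
               "n_genes")
  expect_error(make_genome(small_sim(genome_len = 5000L)), "genome too small")
  g <- make_genome(small_sim())
  intr <- gene_introns(g$models)
  for (gid in g$models$genes$gene_id) {
    n_ex <- sum(primary_exons(g$models)$gene_id == gid)
    expect_equal(sum(intr$gene_id == gid), n_ex - 1L)
  }
  # the duplicated family pair shares one family id
  fam <- g$family_map
  expect_equal(unname(fam[["g002"]]), unname(fam[["g001"]]))
  expect_equal(length(unique(fam)), length(fam) - 1L)
})

test_that("planted in-phase reads share one residue class at fidelity 1", {
  cfg <- small_sim(phasing_fidelity = 1)
  lib <- make_library(cfg)
  aln <- map_reads(lib$reads, lib$genome, 6)
  for (i in seq_len(nrow(lib$truth$loci))) {
    tl <- lib$truth$loci[i, ]
    phased_seqs <- lib$reads$seq[lib$reads$provenance ==
                                   paste0(tl$locus_id, ":phased")]
    sub <- aln[aln$seq %in% phased_seqs & aln$start >= tl$start - 2 &
                 aln$start < tl$end, ]
    ph <- register_position(sub$start, sub$strand, tl$register_len)
    expect_true(all(ph %% tl$register_len == tl$phase_offset))
  }
})

test_that("the truth table lists every planted locus and trigger site", {
  cfg <- small_sim()
  lib <- make_library(cfg)
  expect_equal(nrow(lib$truth$loci), 6L)
  expect_equal(sort(unique(lib$truth$loci$class)),
               c("exon", "exon_intron", "intergenic", "intron"))
  # two-hit loci contribute two cleavage sites, one-hit one
  for (lid in lib$truth$loci$locus_id) {
    tt <- lib$truth$triggers[lib$truth$triggers$locus_id == lid, ]
    expect_equal(nrow(tt),
                 if (tt$model[1] == "two_hit") 2L else 1L)
  }
  # degradome reads planted at every true cleavage site
  expect_setequal(lib$degradome$pos, lib$truth$triggers$cleavage)
})

test_that("rRNA contamination is binomial around its nominal fraction", {
  cfg <- small_sim(rrna_fraction = 0.1)
  lib <- make_library(cfg)
  n_rrna <- sum(lib$reads$count[lib$reads$provenance == "rrna"])
  depth <- sum(lib$reads$count)
  p <- 0.1
  expect_lt(abs(n_rrna - depth * p), 3 * sqrt(depth * p * (1 - p)) + 1)
})

test_that("recovery scoring counts overlaps and false positives", {
  truth <- data.frame(locus_id = c("t1", "t2"), class = c("exon", "intron"),
                      chrom = "chr1", start = c(100L, 1000L),
                      end = c(310L, 1210L), register_len = 21L)
  called <- data.frame(locus_id = c("c1", "c2"), ref_id = "chr1",
                       start = c(63L, 5000L), end = c(315L, 5189L),
                       register_len = 21L)
  r <- score_recovery(called, truth)
  expect_equal(r$sensitivity, 0.5)   # t1 recovered, t2 missed
  expect_equal(r$precision, 0.5)     # c2 is spurious
  expect_equal(score_recovery(called[0, ], truth)$sensitivity, 0)
  perfect <- data.frame(locus_id = "c", ref_id = "chr1", start = 100L,
                        end = 310L, register_len = 21L)
  expect_equal(score_recovery(perfect, truth[1, ])$precision, 1)
})

test_that("sensitivity rises with phasing fidelity", {
  cfgs <- lapply(c(0, 0.9), function(f) small_sim(phasing_fidelity = f))
  sens <- vapply(cfgs, function(cfg) {
    lib <- make_library(cfg)
    aln <- map_reads(filter_rrna(lib$reads, lib$rrna), lib$genome, 6)
    pc <- phas_config()
    w <- scan_windows(aln, vapply(lib$genome, nchar, integer(1)), pc)
    loci <- call_phas_loci(w, aln, pc)
    score_recovery(loci, lib$truth$loci)$sensitivity
  }, numeric(1))
  expect_lt(sens[1], 0.5)
  expect_gt(sens[2], 0.8)
  expect_lt(sens[1], sens[2])
})
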