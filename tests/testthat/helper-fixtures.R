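# Small in-code fixtures shared across test files.

# A seeded random chromosome as a named character vector.
tiny_genome <- function(len = 4000, seed = 7, name = "chr1") {
  set.seed(seed)
  stats::setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""), name)
}

# Alignments of a perfect duplex-complete phased locus: `cycles` sense
# 21-mers at start + i*21 and antisense partners at leftmost -2, all
# distinct sequences drawn from the genome.
duplex_locus_alignments <- function(genome, start, cycles = 10,
                                    register_len = 21, count = 20,
                                    strands = c("+", "-")) {
  g <- genome[[1]]
  rows <- list()
  for (i in seq_len(cycles) - 1) {
    s <- start + i * register_len
    if ("+" %in% strands)
      rows[[length(rows) + 1]] <- data.frame(
        seq = substr(g, s + 1, s + register_len), count = count,
        length = register_len, ref_id = names(genome)[1], strand = "+",
        start = s, hits = 1L, stringsAsFactors = FALSE)
    if ("-" %in% strands)
      rows[[length(rows) + 1]] <- data.frame(
        seq = phasr::revcomp(substr(g, s - 2 + 1, s - 2 + register_len)),
        count = count, length = register_len, ref_id = names(genome)[1],
        strand = "-", start = s - 2, hits = 1L, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# A small two-gene GFF3 written to a temp file; returns the path.
write_tiny_gff3 <- function(path = tempfile(fileext = ".gff3")) {
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t100\t.\t+\t.\tID=gA",
    "chr1\ttest\tmRNA\t1\t100\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\ttest\texon\t1\t30\t.\t+\t.\tParent=gA.t1",
    "chr1\ttest\texon\t61\t100\t.\t+\t.\tParent=gA.t1",
    "chr1\ttest\tgene\t201\t400\t.\t-\t.\tID=gB",
    "chr1\ttest\tmRNA\t201\t400\t.\t-\t.\tID=gB.t1;Parent=gB",
    "chr1\ttest\texon\t201\t260\t.\t-\t.\tParent=gB.t1",
    "chr1\ttest\texon\t301\t400\t.\t-\t.\tParent=gB.t1",
    "chr1\ttest\tmRNA\t201\t400\t.\t-\t.\tID=gB.t2;Parent=gB",
    "chr1\ttest\texon\t201\t400\t.\t-\t.\tParent=gB.t2"
  ), path)
  path
}

# A minimal SAM file; qname carries _<count> suffixes.
write_tiny_sam <- function(path = tempfile(fileext = ".sam")) {
  mer <- function(x) substr(strrep(x, 5), 1, 21)
  rec <- function(qname, flag, pos, cigar, seq, nh) {
    paste(qname, flag, "chr1", pos, 255, cigar, "*", 0, 0, seq, "*",
          paste0("NH:i:", nh), "NM:i:0", sep = "\t")
  }
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:1000",
    rec("r1_17", 0, 101, "21M", mer("ACGTA"), 1),      # kept, 0-based 100
    rec("r2_5", 0, 201, "21M", mer("GATTA"), 7),       # NH=7: dropped
    rec("r3_2", 0, 301, "10M1I10M", mer("CCGGA"), 1),  # gapped: dropped
    rec("r4_3", 16, 401, "21M", mer("TTACG"), 1)       # minus strand
  ), path)
  path
}
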