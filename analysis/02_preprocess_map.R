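#!/usr/bin/env Rscript
# Clean and place the simulated library: rRNA filtering, RPM
# normalisation and exact both-strand mapping with the <= 6-hit rule.

suppressPackageStartupMessages(library(phasr))
dir.create("results", showWarnings = FALSE)

genome <- read_fasta("results/sim/genome.fa")
reads <- read_collapsed_reads("results/sim/reads_collapsed.fa")
rrna <- read_fasta("results/sim/rrna.fa")
cfg <- phas_config()

n_in <- sum(reads$count)
reads <- filter_rrna(reads, rrna)
total <- sum(reads$count)
reads$rpm <- compute_rpm(reads$count, total)
cat(sprintf("rRNA filtering: %d -> %d reads (%.1f%% removed)\n",
            n_in, total, 100 * (n_in - total) / n_in))

aln <- map_reads(reads, genome, cfg$max_hits)
aln$rpm <- compute_rpm(aln$count, total)
drop <- attr(aln, "dropped")
cat(sprintf("mapping: %d placements; dropped %d unmapped, %d multi-hit (> %d)\n",
            nrow(aln), drop["unmapped"], drop["multihit"], cfg$max_hits))
print(table(length = aln$length[aln$length %in% 20:24]))

write.table(aln, "results/alignments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(as.character(total), "results/library_total.txt")
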