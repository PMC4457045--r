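#!/usr/bin/env Rscript
# Build the synthetic study library: a 200-kb genome with 26 gene
# models (one ~85%-identity duplicated family pair), 30 planted 21-nt
# PHAS loci across the four genomic classes, triggers, degradome reads,
# background noise and rRNA contamination. Writes all inputs the later
# stages read, plus the truth tables.

suppressPackageStartupMessages(library(phasr))
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

lib <- make_library(sim_config())

writeLines(c(">chr1", lib$genome[["chr1"]]), "results/sim/genome.fa")
write_gff3(lib$models, "results/sim/genes.gff3")
write_collapsed_fasta(lib$reads, "results/sim/reads_collapsed.fa")
writeLines(c(paste0(">", lib$rrna$id), lib$rrna$seq), "results/sim/rrna.fa")
write.table(lib$degradome, "results/sim/degradome_ends.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(lib$truth$loci, "results/sim/truth_loci.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(lib$truth$triggers, "results/sim/truth_triggers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(gene_id = names(lib$family_map),
                       family = unname(lib$family_map)),
            "results/sim/family_map.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("simulated %d collapsed reads (%d raw) over %d planted loci\n",
            nrow(lib$reads), sum(lib$reads$count), nrow(lib$truth$loci)))
print(table(lib$truth$loci$class))
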