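#!/usr/bin/env Rscript
# Differential phasiRNA production between two libraries, emulating the
# infection-style contrast: library B loses one planted locus entirely
# and produces six-fold more phasiRNAs from another.

suppressPackageStartupMessages(library(phasr))

cfg <- phas_config()

lib <- make_library(sim_config())
truth <- lib$truth$loci

reads_a <- lib$reads
reads_b <- lib$reads[lib$reads$provenance !=
                       paste0(truth$locus_id[1], ":phased"), , drop = FALSE]
sel <- reads_b$provenance == paste0(truth$locus_id[2], ":phased")
reads_b$count[sel] <- reads_b$count[sel] * 6L

run_a <- run_phas_pipeline(reads_a, lib$genome, lib$models, cfg,
                           rrna = lib$rrna, run_triggers = FALSE,
                           run_targets = FALSE)
run_b <- run_phas_pipeline(reads_b, lib$genome, lib$models, cfg,
                           rrna = lib$rrna, run_triggers = FALSE,
                           run_targets = FALSE)
d <- compare_runs(run_a, run_b, cfg)
cat("verdicts across locus keys:\n")
print(table(d$verdict))
cat("most changed loci:\n")
print(head(d[order(abs(log(d$ratio)), decreasing = TRUE), ], 5))
write.table(d, "results/differential.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
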