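#!/usr/bin/env Rscript
# Trigger prediction (one-hit 22-nt vs two-hit models, phase
# consistency, degradome validation) and phasiRNA target prediction
# (cis / same-family / trans), scored against the planted truth.

suppressPackageStartupMessages(library(phasr))

genome <- read_fasta("results/sim/genome.fa")
models <- read_gff3("results/sim/genes.gff3")
reads <- read_collapsed_reads("results/sim/reads_collapsed.fa")
rrna <- read_fasta("results/sim/rrna.fa")
degradome <- read.table("results/sim/degradome_ends.tsv", sep = "\t",
                        header = TRUE,
                        colClasses = c(ref_id = "character",
                                       seq = "character"))
fam <- read.table("results/sim/family_map.tsv", sep = "\t", header = TRUE)
family_map <- setNames(fam$family, fam$gene_id)
truth_tr <- read.table("results/sim/truth_triggers.tsv", sep = "\t",
                       header = TRUE, colClasses = c(seq = "character"))
cfg <- phas_config()

run <- run_phas_pipeline(reads, genome, models, cfg, rrna = rrna,
                         degradome = degradome, family_map = family_map)

tr <- run$triggers
cat(sprintf("retained %d trigger candidates over %d loci\n",
            nrow(tr$candidates), nrow(run$loci[["21"]])))
cat("initiation models:\n")
print(table(tr$models$model))
cat("degradome validation of retained candidates:\n")
print(table(tr$candidates$degradome))
hit <- merge(tr$candidates, truth_tr[, c("seq", "cleavage")],
             by.x = c("seq", "cleavage_pos"), by.y = c("seq", "cleavage"))
cat(sprintf("%d of %d planted trigger sites recovered in phase\n",
            nrow(hit), nrow(truth_tr)))
write.table(tr$candidates, "results/triggers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tr$models, "results/trigger_models.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tg <- run$targets
cat("target predictions by relation (stringent = score <= 1.5):\n")
print(table(tg$relation, stringent = tg$stringent))
write.table(tg, "results/targets.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
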