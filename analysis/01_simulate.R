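#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 12 fibroblast samples (3 WT, 2 UVSS,
# 7 CS across subtypes), two platforms with 7 replicated samples, a platform
# batch shift, and planted differential positions/regions with known truth.
# Writes annotation, beta matrices, sample sheet and truth tables.

suppressMessages(library(progmeth))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(n_islands = 1800, opensea_probes = 3000, seed = 101)
ann <- simulate_annotation(cfg)
sim <- simulate_cohort(cfg, ann)

cat(sprintf("simulated %d probes (%d on X/Y) over %d island blocks\n",
            nrow(ann), sum(ann$chr %in% c("X", "Y")), cfg$n_islands))
cat(sprintf("450k: %d probes x %d samples; EPIC: %d x %d; %d replicated\n",
            nrow(sim$beta_450k), ncol(sim$beta_450k),
            nrow(sim$beta_epic), ncol(sim$beta_epic),
            sum(grepl(",", sim$sheet$platforms))))
cat(sprintf("planted: %d DMPs, %d DMRs, %d UVSS-intermediate regions (effect %.2f)\n",
            nrow(sim$truth$dmp), sum(!sim$truth$dmr$uvss_intermediate),
            length(sim$truth$uvss_intermediate), cfg$dmr_effect))

write_annotation_csv(ann, "results/annotation.csv")
write_beta_tsv(sim$beta_450k, "results/beta_450k.tsv")
write_beta_tsv(sim$beta_epic, "results/beta_epic.tsv")
write_sample_sheet(sim$sheet, "results/sample_sheet.tsv")
write.table(sim$truth$dmp, "results/truth_dmp.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth$dmr, "results/truth_dmr.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/{annotation.csv,beta_450k.tsv,beta_epic.tsv,sample_sheet.tsv,truth_*.tsv}\n")
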