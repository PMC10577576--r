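#!/usr/bin/env Rscript
# Differential methylation: per-probe ANOVA DMPs (BH < 0.05, |delta| > 10%),
# sliding-window MANOVA DMRs on island blocks, the stringent separation
# filter, island-relation enrichment, and a BED export. Compares calls with
# the planted truth.

suppressMessages(library(progmeth))

beta <- read_beta_tsv("results/beta_processed.tsv")
sheet <- read_sample_sheet("results/sample_sheet.tsv")
ann <- read_annotation_csv("results/annotation.csv")
truth_dmp <- read.delim("results/truth_dmp.tsv", stringsAsFactors = FALSE)
truth_dmr <- read.delim("results/truth_dmr.tsv", stringsAsFactors = FALSE)

dmp <- call_dmps(beta, sheet)
cat(sprintf("DMPs: %d of %d tested probes (%.1f%% hypo)\n",
            sum(dmp$is_dmp), sum(!is.na(dmp$p_adj)),
            100 * mean(dmp$direction[dmp$is_dmp] == "hypo")))
cat(sprintf("planted isolated DMPs recovered: %d / %d\n",
            sum(truth_dmp$probe_id %in% dmp$probe_id[dmp$is_dmp]),
            nrow(truth_dmp)))

dmr <- call_dmrs(beta, sheet, ann, dmp_table = dmp)
cat(sprintf("DMRs: %d merged regions from %d windows (%d blocks too short)\n",
            nrow(dmr), attr(dmr, "n_windows"), attr(dmr, "n_blocks_skipped")))
planted <- truth_dmr$island_id[!truth_dmr$uvss_intermediate]
cat(sprintf("planted regions recovered: %d / %d; direction concordant: %d\n",
            sum(planted %in% dmr$island_id), length(planted),
            sum(dmr$direction[match(planted, dmr$island_id)] ==
                  ifelse(truth_dmr$effect[!truth_dmr$uvss_intermediate] > 0,
                         "hyper", "hypo"), na.rm = TRUE)))

strin <- stringent_filter(dmr, beta, sheet, gap_min = 0.1)
inter <- truth_dmr$island_id[truth_dmr$uvss_intermediate]
cat(sprintf("StringentDMRs (gap 0.1): %d; UVSS-intermediate among them: %d / %d planted\n",
            sum(strin$is_stringent),
            sum(strin$island_id[strin$is_stringent] %in% inter),
            length(inter)))

enr <- region_enrichment(dmp, ann)
sig <- enr[enr$p < 0.05, c("category", "direction", "odds_ratio", "p")]
cat("island-relation categories enriched/depleted at p < 0.05:\n")
if (nrow(sig)) print(sig, row.names = FALSE) else cat("  (none)\n")

write.table(dmp, "results/dmp_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(strin, "results/dmr_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(enr, "results/region_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
export_dmrs_bed(strin, ann, "results/dmrs.bed")
cat("wrote results/{dmp_table,dmr_table,region_enrichment}.tsv, results/dmrs.bed\n")
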