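#!/usr/bin/env Rscript
# Preprocess the dual-platform cohort: intersect probes, adjust the platform
# batch effect (parametric empirical-Bayes, phenotype protected), drop X/Y
# probes, average replicated samples; then PCA and hierarchical clustering
# overviews. Writes the processed beta matrix and the PCA scores.

suppressMessages(library(progmeth))

b450 <- read_beta_tsv("results/beta_450k.tsv")
bep <- read_beta_tsv("results/beta_epic.tsv")
sheet <- read_sample_sheet("results/sample_sheet.tsv")
ann <- read_annotation_csv("results/annotation.csv")

ip <- intersect_platforms(b450, bep)
cat(sprintf("probes shared between platforms: %d\n", nrow(ip$m450)))

comb <- combine_platforms(ip$m450, ip$mepic)
phen <- sheet$phenotype[match(comb$sample_id, sheet$sample_id)]

# platform separation before adjustment
pc0 <- pca_overview(comb$beta, k = 2)
adj <- suppressWarnings(combat_adjust(comb$beta, comb$batch, covariate = phen))
pc1 <- pca_overview(adj, k = 2)
sep <- function(pc, lab) abs(mean(pc$scores[lab == "450k", 1]) -
                             mean(pc$scores[lab == "EPIC", 1]))
cat(sprintf("PC1 platform separation before/after ComBat: %.2f / %.2f\n",
            sep(pc0, comb$batch), sep(pc1, comb$batch)))

rep_ids <- intersect(colnames(ip$m450), colnames(ip$mepic))
xcor <- function(m) mean(vapply(rep_ids, function(s)
  cor(m[, paste0(s, "@450k")], m[, paste0(s, "@EPIC")]), numeric(1)))
cat(sprintf("replicate cross-platform correlation before/after: %.4f / %.4f\n",
            xcor(comb$beta), xcor(adj)))

noxy <- drop_sex_probes(adj, ann)
cat(sprintf("autosomal probes retained: %d (removed %d on X/Y)\n",
            nrow(noxy), nrow(adj) - nrow(noxy)))
beta <- merge_replicates(noxy)
cat(sprintf("after replicate averaging: %d probes x %d samples\n",
            nrow(beta), ncol(beta)))

pc <- pca_overview(beta, k = 3)
cat(sprintf("explained variance PC1-3: %s\n",
            paste(sprintf("%.1f%%", 100 * pc$explained), collapse = " ")))
hc <- hierarchical_cluster(beta)
agree <- table(hc$labels, sheet$phenotype[match(names(hc$labels),
                                               sheet$sample_id)])
cat("2-cluster cut vs phenotype:\n"); print(agree)

write_beta_tsv(beta, "results/beta_processed.tsv")
scores <- data.frame(sample_id = rownames(pc$scores), pc$scores,
                     check.names = FALSE)
write.table(scores, "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/beta_processed.tsv, results/pca_scores.tsv\n")
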