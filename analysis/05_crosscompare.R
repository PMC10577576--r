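#!/usr/bin/env Rscript
# Cross-dataset concordance and methylation-expression integration. Two
# additional synthetic cohorts stand in for external disease/ageing datasets:
# one sharing the reference cohort's planted regions (same signs, like normal
# ageing MSCs), one with opposed signs (like a divergent progeroid model).
# Then expression is simulated with partial inverse coupling and correlated
# with regional methylation.

suppressMessages(library(progmeth))

beta <- read_beta_tsv("results/beta_processed.tsv")
sheet <- read_sample_sheet("results/sample_sheet.tsv")
ann <- read_annotation_csv("results/annotation.csv")
dmp <- read.delim("results/dmp_table.tsv", stringsAsFactors = FALSE)
truth_dmr <- read.delim("results/truth_dmr.tsv", stringsAsFactors = FALSE)

ref_delta <- setNames(dmp$delta, dmp$probe_id)
ref <- dataset_delta("CS", ref_delta, dmp$probe_id[dmp$is_dmp])

# companion datasets: external studies enter this comparison as per-probe
# delta tables with their own significance calls, so the stand-ins are built
# the same way — sharing (or opposing) the reference cohort's planted effects
# plus dataset-specific noise
truth_dmp <- read.delim("results/truth_dmp.tsv", stringsAsFactors = FALSE)
planted_eff <- c(setNames(truth_dmp$effect, truth_dmp$probe_id),
                 setNames(rep(truth_dmr$effect,
                              lengths(strsplit(truth_dmr$probe_ids, ","))),
                          unlist(strsplit(truth_dmr$probe_ids, ","))))
planted_eff <- planted_eff[names(planted_eff) %in% names(ref_delta)]
make_companion <- function(label, sign, seed) {
  set.seed(seed)
  d <- setNames(rnorm(length(ref_delta), 0, 0.02), names(ref_delta))
  d[names(planted_eff)] <- d[names(planted_eff)] + sign * planted_eff
  sig <- union(names(planted_eff),
               sample(names(ref_delta), 50))  # own calls incl. false positives
  dataset_delta(label, d, sig)
}
msc <- make_companion("MSC_ageing", +1, 102)
hgps <- make_companion("HGPS_like", -1, 103)

cm_all <- delta_correlation_matrix(list(ref, msc, hgps))
cat("delta correlation (all shared probes):\n"); print(round(cm_all, 3))
cm_dmp <- delta_correlation_matrix(list(ref, msc, hgps),
                                   probe_subset = ref$significant)
cat("delta correlation restricted to CS DMPs:\n"); print(round(cm_dmp, 3))
cat(sprintf("CS-MSC correlation increases on the DMP subset: %s\n",
            cm_dmp["CS", "MSC_ageing"] > cm_all["CS", "MSC_ageing"]))

universe <- intersect(names(ref$delta), names(msc$delta))
ov <- overlap_test(intersect(ref$significant, universe),
                   intersect(msc$significant, universe),
                   universe, ref$delta, msc$delta)
cat(sprintf("DMP overlap CS vs MSC: %d common, OR %.2f, p %.3g, %.1f%% concordant\n",
            ov$n_common, ov$odds_ratio, ov$p, ov$pct_concordant))

# methylation-expression correlation on planted regions
ex <- simulate_expression(beta, ann, list(dmr = truth_dmr),
                          inverse_fraction = 0.6, noise_sd = 0.3, seed = 105)
rows <- lapply(rownames(ex$expr), function(g) {
  i <- which(vapply(truth_dmr$island_id, function(id)
    g %in% ann$genes[ann$island_id == id], logical(1)))
  if (!length(i)) return(NULL)
  pr <- intersect(strsplit(truth_dmr$probe_ids[i[1]], ",")[[1]], rownames(beta))
  cc <- methylation_expression_correlation(colMeans(beta[pr, , drop = FALSE]),
                                           ex$expr[g, ])
  data.frame(gene = g, r = cc$r, r_squared = cc$r_squared, p = cc$p,
             strength = cc$strength, stringsAsFactors = FALSE)
})
tab <- do.call(rbind, rows)
cat(sprintf("meth-expr correlations on %d planted genes: %d significant negative (planted inverse fraction 0.6)\n",
            nrow(tab), sum(tab$p < 0.05 & tab$r < 0, na.rm = TRUE)))
write.table(tab, "results/meth_expr_correlation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/meth_expr_correlation.tsv\n")
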