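#!/usr/bin/env Rscript
# Gene-set scoring of differentially methylated genes with probe-count
# adjustment: best-probe Sidak aggregation to gene p-values, then logistic
# gene-set tests against (a) the set of genes carrying planted regions
# (positive control) and (b) the packaged synthetic control sets.

suppressMessages(library(progmeth))

dmp <- read.delim("results/dmp_table.tsv", stringsAsFactors = FALSE)
ann <- read_annotation_csv("results/annotation.csv")
truth_dmr <- read.delim("results/truth_dmr.tsv", stringsAsFactors = FALSE)

scores <- aggregate_gene_p(dmp, ann)
cat(sprintf("scored %d genes (1-%d probes per gene)\n",
            nrow(scores), max(scores$n_probes)))

planted_genes <- unique(unlist(lapply(truth_dmr$island_id, function(id)
  setdiff(ann$genes[ann$island_id == id], ""))))
sets <- read_gmt(system.file("extdata", "synthetic_gene_sets.gmt",
                             package = "progmeth"))
sets$PLANTED_REGION_GENES <- list(set_id = "PLANTED_REGION_GENES",
                                  description = "genes of planted regions",
                                  genes = planted_genes)

out <- geneset_test_all(scores, sets, seed = 106)
print(out, row.names = FALSE)
cat(sprintf("positive-control set p = %.3g; control sets minimum p = %.3g\n",
            out$p[out$set_id == "PLANTED_REGION_GENES"],
            min(out$p[out$set_id != "PLANTED_REGION_GENES"])))
write.table(out, "results/geneset_tests.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/geneset_tests.tsv\n")
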