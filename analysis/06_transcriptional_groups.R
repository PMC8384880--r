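#!/usr/bin/env Rscript
# Step 6 — pan-cancer transcriptional grouping.
#
# Selects the 300 most variable genes by MAD (the cohort simulates 400),
# consensus-clusters the samples with automatic k selection, reports
# per-group differentially expressed genes, per-model cluster-shift scores,
# and a cis/trans test for a spiked mutated gene.

suppressPackageStartupMessages(library(pdxkit))

cohort <- read_cohort("results/cohort")
kept <- utils::read.delim("results/mutations_filtered.tsv")

centers <- cohort$samples$center[match(colnames(cohort$expression),
                                       cohort$samples$sample_id)]
expr <- center_adjust(cohort$expression, centers)
vg <- select_variable_genes(expr, top_n = 300)
cc <- consensus_cluster(expr[vg, ], k_range = 2:6, iterations = 200,
                        seed = 20260928)
utils::write.table(cc$assignments, "results/expression_groups.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("chosen k = %d (PAC: %s)", cc$k,
                paste(names(cc$pac), round(cc$pac, 3), sep = "=",
                      collapse = ", ")))

degs <- group_degs(expr[vg, ], cc$assignments)
utils::write.table(degs, "results/group_degs.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("%d positive DEGs across %d groups", nrow(degs), cc$k))

shift <- model_shift_scores(cc$assignments, cohort$samples)
utils::write.table(shift, "results/cluster_shift_scores.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("cluster-shift score: median %.2f, %d/%d models fully stable",
                stats::median(shift$score), sum(shift$score == 1),
                nrow(shift)))

# cis/trans for the most recurrently mutated spiked gene
query <- names(sort(table(kept$gene[kept$gene %in% rownames(expr) &
                                    kept$effect == "non_silent"]),
                    decreasing = TRUE))[1]
if (!is.na(query)) {
  ct <- cis_trans_test(expr, kept, query)
  if (!is.null(ct)) {
    utils::write.table(ct, "results/cis_trans.tsv", sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cis <- ct[ct$relation == "cis", ]
    message(sprintf("cis effect of %s: direction %s, FDR %.3g (%d mutated vs %d WT)",
                    query, cis$direction, cis$fdr, cis$n_mut, cis$n_wt))
  }
}
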