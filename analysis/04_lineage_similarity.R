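#!/usr/bin/env Rscript
# Step 4 — mutational similarity across the lineage.
#
# Computes Jaccard mutational similarity for all sample pairs, summarizes
# intra- vs inter-model similarity per case, and scores each model against
# its originating human tumor (flagging scores < 0.2, the regime where the
# engraftment bottleneck or low purity has washed out most mutations).

suppressPackageStartupMessages(library(pdxkit))

cohort <- read_cohort("results/cohort")
kept <- utils::read.delim("results/mutations_filtered.tsv")

sm <- similarity_matrix(kept, cohort$samples)
utils::write.table(sm$pairs, "results/similarity_pairs.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cs <- case_similarity_summary(kept, cohort$samples)
utils::write.table(cs, "results/similarity_by_case.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
hp <- human_pdx_similarity(kept, cohort$samples)
utils::write.table(hp, "results/similarity_human_pdx.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

ok <- !is.na(cs$mean_intra) & !is.na(cs$mean_inter)
message(sprintf("mean intra-model similarity %.3f vs inter-model %.3f (%d cases)",
                mean(cs$mean_intra[ok]), mean(cs$mean_inter[ok]), sum(ok)))
message(sprintf("median human-vs-PDX model score %.3f; %d/%d models flagged < 0.2",
                stats::median(hp$score), sum(hp$low_similarity), nrow(hp)))
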