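#!/usr/bin/env Rscript
# Step 5 — copy-number features, WGD, TP53 LOH, and their associations.
#
# Quality-filters segments, categorizes log2 ratios, computes per-sample
# deletion/amplification genome fractions, calls WGD from allele-specific
# copy numbers, detects TP53 LOH from SNP allelic imbalance in the 6 Mb
# window, flags subclonality, and tests pairwise associations between the
# binary features with Pearson's chi-squared (no continuity correction).

suppressPackageStartupMessages(library(pdxkit))

cohort <- read_cohort("results/cohort")
feats <- sample_cn_features(cohort)
utils::write.table(feats, "results/cn_features.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

assoc <- list()
for (pair in list(c("wgd", "tp53_loh"), c("wgd", "deletion_abundant"),
                  c("deletion_abundant", "tp53_loh"))) {
  res <- tryCatch(association_test(feats[[pair[1]]], feats[[pair[2]]]),
                  error = function(e) NULL)
  if (is.null(res)) next
  assoc[[paste(pair, collapse = "_vs_")]] <-
    list(chi2 = res$chi2, p_value = res$p_value)
  message(sprintf("%s vs %s: chi2 = %.2f, p = %.3g", pair[1], pair[2],
                  res$chi2, res$p_value))
}
jsonlite::write_json(assoc, "results/cn_associations.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message(sprintf("WGD in %d/%d samples (%.0f%%); deletion-abundant in %d",
                sum(feats$wgd), nrow(feats), 100 * mean(feats$wgd),
                sum(feats$deletion_abundant)))
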