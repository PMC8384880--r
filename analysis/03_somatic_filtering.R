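#!/usr/bin/env Rscript
# Step 3 — somatic variant filter cascade.
#
# Applies the tumor/normal consensus filter (or the tumor-only filter where
# no human normal exists), the PDX-specific false-positive filter
# (whitelist or matched-human evidence), and the indel-proximity filter,
# and writes the retained call set plus per-rule failure counts.

suppressPackageStartupMessages(library(pdxkit))

cohort <- read_cohort("results/cohort")
kept <- filter_cohort_mutations(cohort)
utils::write.table(kept, "results/mutations_filtered.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# per-rule audit on the first cascade stage, across all tumor samples
d <- consensus_filter(cohort$mutations[!is.na(cohort$mutations$n_depth), ])
rules <- unlist(strsplit(d$failed_rules[d$failed_rules != ""], ";"))
message(sprintf("retained %d of %d calls (%.1f%%)", nrow(kept),
                nrow(cohort$mutations),
                100 * nrow(kept) / nrow(cohort$mutations)))
message("consensus-stage failure counts: ",
        paste(names(sort(table(rules), decreasing = TRUE)),
              sort(table(rules), decreasing = TRUE),
              sep = "=", collapse = ", "))
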