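#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
#
# Generates the synthetic pan-cancer PDX cohort all later steps analyze:
# 12 cases, 1-2 models each, 2-3 passages per model, matched human
# tumor/normal pairs, treatment-arm alterations spiked into known druggable
# genes, plus one planted cross-case swap and one 30% contamination so the
# identity-QC step has something to find. Everything is written under
# results/cohort/ in the standard formats (per-sample VCF, MAF-like TSV,
# SEG TSV, expression TSV, lineage/truth JSON).

suppressPackageStartupMessages(library(pdxkit))

seed <- 20260928L
out_dir <- "results/cohort"

spikes <- data.frame(
  arm_id = c("ARM-PIK3CA", "ARM-ERBB2", "ARM-PTEN", "ARM-FGFR", "ARM-CCND1"),
  gene   = c("PIK3CA", "ERBB2", "PTEN", "FGFR3", "CCND1"),
  class  = c("non_silent_mutation", "amplification", "deletion", "fusion",
             "amplification"),
  n_models = c(5, 4, 3, 3, 4))

cfg <- cohort_config(seed = seed, n_cases = 12, models_per_case = c(1, 2),
                     passages_per_model = c(2, 3), arm_spikes = spikes)
cohort <- generate_cohort(cfg)

anomalies <- data.frame(
  type = c("swap", "contaminate"),
  sample_a = c("case001_M1_P0", "case004_M1_P0"),
  sample_b = c("case002_HT", "case006_HT"),
  frac = c(NA, 0.3))
cohort <- plant_anomalies(cohort, anomalies)

write_cohort(cohort, out_dir)
message(sprintf("cohort: %d samples, %d cases, %d mutation calls, %d segments",
                nrow(cohort$samples), length(unique(cohort$samples$case_id)),
                nrow(cohort$mutations), nrow(cohort$segments)))
message(sprintf("planted: %d arm spike-ins, 1 swap, 1 contamination (30%%)",
                nrow(cohort$truth$arm_truth)))
message("written to ", out_dir)
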