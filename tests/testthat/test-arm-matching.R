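alt_row <- function(gene = "PIK3CA", class = "non_silent_mutation",
                    variant = NA_character_, sample_id = "s1") {
  data.frame(sample_id = sample_id, gene = gene, class = class,
             variant = variant, stringsAsFactors = FALSE)
}

test_that("arm matching honors criteria, exclusions, and biomarkers", {
  rules <- example_arm_rules()
  # PIK3CA non-silent mutation matches the copanlisib arm
  m <- match_alterations_to_arms(alt_row(), "BRCA", rules)
  expect_true("ARM-PIK3CA" %in% m$arm_id)
  # the same alteration in an excluded disease does not match
  braf <- alt_row("BRAF", "non_silent_mutation", variant = "V600E")
  expect_true("ARM-BRAF" %in%
              match_alterations_to_arms(braf, "SKCM", rules)$arm_id)
  expect_false("ARM-BRAF" %in%
               match_alterations_to_arms(braf, "COAD", rules)$arm_id)
  # variant whitelist requires the exact protein change
  braf_other <- alt_row("BRAF", "non_silent_mutation", variant = "G469A")
  expect_false("ARM-BRAF" %in%
               match_alterations_to_arms(braf_other, "SKCM", rules)$arm_id)
  # gene-level amplification matches the ERBB2 arm
  m2 <- match_alterations_to_arms(alt_row("ERBB2", "amplification"),
                                  "BRCA", rules)
  expect_true("ARM-ERBB2" %in% m2$arm_id)
  # fusion matches via either partner
  m3 <- match_alterations_to_arms(alt_row("FGFR3", "fusion"), "HNSC", rules)
  expect_true("ARM-FGFR" %in% m3$arm_id)
  # unknown cancer type passes through with a warning
  expect_warning(m4 <- match_alterations_to_arms(braf, NA, rules),
                 "unknown cancer type")
  expect_true("ARM-BRAF" %in% m4$arm_id)
  # biomarker requirement must hold
  rules_bm <- rules
  rules_bm[[1]]$biomarkers <- list(her2 = "positive")
  expect_equal(nrow(match_alterations_to_arms(alt_row(), "BRCA", rules_bm)), 0)
  m5 <- match_alterations_to_arms(alt_row(), "BRCA", rules_bm,
                                  biomarkers = list(her2 = "positive"))
  expect_true("ARM-PIK3CA" %in% m5$arm_id)
})

test_that("matching is monotone in alterations and exclusions", {
  rules <- example_arm_rules()
  set.seed(41)
  genes <- c("PIK3CA", "ERBB2", "CCND1", "PTEN", "FGFR3", "BG001")
  classes <- c("non_silent_mutation", "amplification", "deletion", "fusion")
  for (i in 1:50) {
    n <- sample(1:5, 1)
    alts <- do.call(rbind, lapply(seq_len(n), function(j) {
      alt_row(sample(genes, 1), sample(classes, 1))
    }))
    base_arms <- match_alterations_to_arms(alts, "BRCA", rules)$arm_id
    more <- rbind(alts, alt_row(sample(genes, 1), sample(classes, 1)))
    more_arms <- match_alterations_to_arms(more, "BRCA", rules)$arm_id
    expect_true(all(base_arms %in% more_arms))
    # adding an exclusion never adds a match
    rules_x <- rules
    rules_x[[1]]$exclusions <- c(rules_x[[1]]$exclusions, "BRCA")
    excl_arms <- match_alterations_to_arms(alts, "BRCA", rules_x)$arm_id
    expect_true(all(excl_arms %in% base_arms))
  }
})

test_that("model classification partitions by matched-arm count", {
  matches <- data.frame(model_id = c("m1", "m2", "m2"),
                        arm_id = c("A", "A", "B"))
  cl <- classify_models(matches, c("m1", "m2", "m3"))
  expect_equal(cl$single_arm, "m1")
  expect_equal(cl$multi_arm, "m2")
  expect_equal(cl$unmatched, "m3")
  # constructed cohort of 10 models: 6 single, 4 multi
  mm <- rbind(data.frame(model_id = paste0("s", 1:6), arm_id = "A"),
              data.frame(model_id = rep(paste0("d", 1:4), each = 2),
                         arm_id = rep(c("A", "B"), 4)))
  cl2 <- classify_models(mm, c(paste0("s", 1:6), paste0("d", 1:4)))
  expect_equal(length(cl2$single_arm) / 10, 0.6)
  expect_equal(length(cl2$multi_arm) / 10, 0.4)
})

test_that("S_arm is the fraction of positive passage bins", {
  samples <- data.frame(
    sample_id = paste0("p", 0:3), model_id = "m1", sample_class = "pdx",
    passage_index = 0:3, stringsAsFactors = FALSE)
  all_pos <- s_arm_score(paste0("p", 0:3), "m1", samples)
  expect_equal(all_pos$s_arm, 1)
  expect_equal(all_pos$n_pb, 4L)
  half <- s_arm_score(paste0("p", 0:1), "m1", samples)
  expect_equal(half$s_arm, 0.5)
  none <- s_arm_score(character(0), "m1", samples)
  expect_equal(none$s_arm, 0)
  # no PDX samples: undefined score
  expect_null(s_arm_score("p0", "m1", samples[0, ]))
})

test_that("S_arm equals brute force over random positivity patterns", {
  set.seed(43)
  for (i in 1:2000) {
    n <- sample(2:12, 1)
    samples <- data.frame(
      sample_id = paste0("p", seq_len(n)),
      model_id = sample(c("m1", "m2"), n, TRUE),
      sample_class = "pdx",
      passage_index = sample(0:4, n, TRUE), stringsAsFactors = FALSE)
    pos <- samples$sample_id[stats::runif(n) < 0.4]
    matched <- unique(samples$model_id)
    got <- s_arm_score(pos, matched, samples)
    bins <- sort(unique(samples$passage_index))
    pos_bins <- vapply(bins, function(b) {
      any(samples$sample_id %in% pos & samples$passage_index == b)
    }, TRUE)
    expect_equal(got$s_arm, sum(pos_bins) / length(bins))
    expect_equal(got$n_pb, length(bins))
    # S_arm lives on the grid {0, 1/N, ..., 1}; 1 iff every bin positive
    expect_true(got$s_arm %in% ((0:got$n_pb) / got$n_pb))
    expect_equal(got$s_arm == 1, all(pos_bins))
  }
})

test_that("kinase fusions classify by partner and obey the FFPM filter", {
  kin <- c("FGFR3", "BRAF")
  fus <- data.frame(
    gene5 = c("FGFR3", "TACC3", "FGFR3", "FGFR3", "FGFR3"),
    gene3 = c("TACC3", "FGFR3", "BRAF", "TACC3", "TACC3"),
    ffpm = c(1, 1, 1, 0.05, 0.1),
    annotation_tags = c("", "", "", "", ""), stringsAsFactors = FALSE)
  out <- kinase_fusion_classify(fus, kin)
  expect_equal(out$kinase_class,
               c("five_prime", "three_prime", "both", "five_prime",
                 "five_prime"))
  expect_equal(out$keep, c(TRUE, TRUE, TRUE, FALSE, FALSE))  # ffpm <= 0.1 drops
  # normal-panel annotation drops regardless of FFPM
  fus$annotation_tags[1] <- "Greger_Normal"
  expect_false(kinase_fusion_classify(fus, kin)$keep[1])
  # no kinase partner
  none <- kinase_fusion_classify(
    data.frame(gene5 = "A", gene3 = "B", ffpm = 1, annotation_tags = ""), kin)
  expect_equal(none$kinase_class, "none")
})

test_that("alteration-expression association applies both pass legs", {
  set.seed(44)
  amp <- c(rnorm(8, 8, 0.3), rnorm(20, 2, 0.3))   # 4x means, log2FC = 2
  altered <- rep(c(TRUE, FALSE), c(8, 20))
  res <- alteration_expression_association(amp, altered)
  expect_true(res$pass)
  expect_equal(res$log2_fc, log2(mean(amp[1:8]) / mean(amp[-(1:8)])))
  # identical groups fail
  same <- alteration_expression_association(rep(5, 28) + rnorm(28, 0, 1e-3),
                                            altered)
  expect_false(same$pass)
  # log2FC below 0.585 fails even with small p
  weak <- c(rnorm(8, 5.6, 0.01), rnorm(20, 4, 0.01))  # log2FC ~ 0.49
  res3 <- alteration_expression_association(weak, altered)
  expect_lt(res3$p_value, 0.01)
  expect_false(res3$pass)
  expect_null(alteration_expression_association(amp, rep(FALSE, 28)))
})

test_that("end-to-end arm matching equals the spike-in truth", {
  spikes <- data.frame(
    arm_id = c("ARM-PIK3CA", "ARM-ERBB2", "ARM-PTEN", "ARM-FGFR"),
    gene = c("PIK3CA", "ERBB2", "PTEN", "FGFR3"),
    class = c("non_silent_mutation", "amplification", "deletion", "fusion"),
    n_models = c(3, 2, 2, 2), stringsAsFactors = FALSE)
  cfg <- cohort_config(seed = 23, n_cases = 5, models_per_case = 2,
                       passages_per_model = 2, n_snp_loci = 10,
                       n_genes = 120, signature_size = 10,
                       arm_spikes = spikes)
  co <- generate_cohort(cfg)
  res <- cohort_arm_matching(co)
  got <- res$model_matches[order(res$model_matches$arm_id,
                                 res$model_matches$model_id), ]
  want <- unique(co$truth$arm_truth[, c("model_id", "arm_id")])
  want <- want[order(want$arm_id, want$model_id), ]
  expect_equal(got$model_id, want$model_id)
  expect_equal(got$arm_id, want$arm_id)
  # classification partitions all models
  cl <- res$classification
  expect_equal(sort(c(cl$single_arm, cl$multi_arm, cl$unmatched)),
               sort(unique(co$samples$model_id[!is.na(co$samples$model_id)])))
  # spiked alterations are clonal in their models: every bin positive
  for (sc in res$arm_scores) expect_equal(sc$s_arm, 1)
})
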