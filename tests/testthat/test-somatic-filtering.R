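tn_call <- function(callers = "mutect,strelka", t_depth = 20L, t_alt = 5L,
                    n_depth = 10L, n_alt = 0L, pos = 100L,
                    variant_type = "snv", whitelist = FALSE) {
  data.frame(sample_id = "s1", chrom = "chr1", pos = pos, ref = "A", alt = "G",
             variant_type = variant_type, callers = callers,
             t_depth = t_depth, t_alt = t_alt, n_depth = n_depth,
             n_alt = n_alt, whitelist = whitelist, stringsAsFactors = FALSE)
}

test_that("tumor/normal consensus filter honors every stated threshold", {
  # retained: 2 callers, depths 20/10, 5 alt reads, VAFs 0.25 / 0
  expect_true(consensus_filter(tn_call())$retained)
  # single caller removed with the min_callers rule recorded
  d <- consensus_filter(tn_call(callers = "mutect"))
  expect_false(d$retained)
  expect_equal(d$failed_rules, "min_callers")
  # boundary values are retained (discard rules are strict)
  d <- consensus_filter(tn_call(t_depth = 80L, t_alt = 4L,
                                n_depth = 100L, n_alt = 1L))
  expect_true(d$retained)   # t_VAF = 0.05, n_VAF = 0.01 exactly
  # each threshold fails one step below its bound
  expect_false(consensus_filter(tn_call(t_depth = 13L))$retained)
  expect_false(consensus_filter(tn_call(n_depth = 7L))$retained)
  expect_false(consensus_filter(tn_call(t_alt = 3L, t_depth = 30L))$retained)
  expect_false(consensus_filter(tn_call(t_depth = 90L, t_alt = 4L))$retained)
  expect_false(consensus_filter(tn_call(n_depth = 90L, n_alt = 1L))$retained)
  # missing normal counts direct to the tumor-only cascade
  expect_error(consensus_filter(tn_call(n_depth = NA_integer_,
                                        n_alt = NA_integer_)),
               "tumor_only_filter")
})

test_that("tumor-only filter requires 20x, >3 alt reads, VAF >= 0.1", {
  expect_true(tumor_only_filter(tn_call(t_depth = 25L, t_alt = 4L))$retained)
  expect_false(tumor_only_filter(tn_call(t_depth = 25L, t_alt = 3L))$retained)
  d <- tumor_only_filter(tn_call(t_depth = 100L, t_alt = 9L))  # VAF 0.09
  expect_false(d$retained)
  expect_equal(d$failed_rules, "min_t_vaf")
  expect_false(tumor_only_filter(tn_call(t_depth = 19L, t_alt = 5L))$retained)
  expect_true(tumor_only_filter(tn_call(t_depth = 40L, t_alt = 4L))$retained)
})

test_that("PDX false-positive filter uses whitelist or matched human evidence", {
  pdx <- tn_call()
  human_same <- tn_call()
  human_other <- tn_call(pos = 999L)
  expect_true(pdx_fp_filter(pdx, human_same)$retained)
  expect_false(pdx_fp_filter(pdx, human_other)$retained)
  expect_true(pdx_fp_filter(tn_call(whitelist = TRUE), NULL)$retained)
  expect_false(pdx_fp_filter(pdx, NULL)$retained)
})

test_that("SNVs within 20 bp of a retained indel are removed, boundary exact", {
  mk <- function(snv_pos, indel_pos) {
    rbind(tn_call(pos = snv_pos),
          tn_call(pos = indel_pos, variant_type = "indel"))
  }
  d <- indel_proximity_filter(mk(100L, 115L))
  expect_equal(d$retained, c(FALSE, TRUE))
  d <- indel_proximity_filter(mk(100L, 121L))       # |delta| = 21
  expect_equal(d$retained, c(TRUE, TRUE))
  d <- indel_proximity_filter(mk(100L, 120L))       # |delta| = 20 inclusive
  expect_equal(d$retained, c(FALSE, TRUE))
  # no indels: identity
  d <- indel_proximity_filter(rbind(tn_call(pos = 1L), tn_call(pos = 2L)))
  expect_true(all(d$retained))
  # different chromosome or sample does not trigger the window
  two <- mk(100L, 110L)
  two$chrom[2] <- "chr2"
  expect_true(all(indel_proximity_filter(two)$retained))
})

test_that("germline post-filters apply AD, VAF, cohort MAF, population AF, gene list", {
  gl <- function(ad_alt = 9L, depth = 20L, pop_af = 1e-4, gene = "BRCA1") {
    data.frame(sample_id = "s1", chrom = "chr1", pos = 50L, ref = "A",
               alt = "T", gene = gene, ad_alt = ad_alt, depth = depth,
               pop_af = pop_af, stringsAsFactors = FALSE)
  }
  genes <- c("BRCA1", "BRCA2", "TP53")
  # retained: AD 9, VAF 0.45, cohort MAF 1/500, pop AF 0.01%
  expect_true(germline_post_filter(gl(), genes, n_samples = 500)$retained)
  # VAF 0.15 removed
  expect_false(germline_post_filter(gl(ad_alt = 3L), genes, 500)$retained)
  expect_false(germline_post_filter(gl(ad_alt = 6L, depth = 40L),
                                    genes, 500)$retained)
  # population AF 0.2% removed; exactly 0.05% retained
  expect_false(germline_post_filter(gl(pop_af = 0.002), genes, 500)$retained)
  expect_true(germline_post_filter(gl(pop_af = 5e-4), genes, 500)$retained)
  # gene outside the predisposition list removed
  expect_false(germline_post_filter(gl(gene = "XYZ"), genes, 500)$retained)
  # cohort MAF > 1% removed: same key in 6 of 500 samples
  common <- do.call(rbind, lapply(1:6, function(i) {
    g <- gl(); g$sample_id <- paste0("s", i); g
  }))
  d <- germline_post_filter(common, genes, n_samples = 500)
  expect_false(any(d$retained))
  expect_true(all(grepl("cohort_maf", d$failed_rules)))
  # missing population AF treated as 0 with a warning
  expect_warning(d <- germline_post_filter(gl(pop_af = NA), genes, 500),
                 "missing population AF")
  expect_true(d$retained)
  # tumor-only mode drops keys present in the somatic or whitelist sets
  d <- germline_post_filter(gl(), genes, 500, tumor_only = TRUE,
                            somatic_keys = "chr1:50:A:T")
  expect_false(d$retained)
})

test_that("cascades equal an independently coded brute-force evaluator", {
  calls <- random_calls(1000, seed = 101, mode = "tn")
  expect_equal(consensus_filter(calls)$retained, oracle_consensus(calls))
  to <- random_calls(1000, seed = 102, mode = "to")
  expect_equal(tumor_only_filter(to)$retained, oracle_tumor_only(to))
  human <- random_calls(300, seed = 103, mode = "tn")
  expect_equal(pdx_fp_filter(calls, human)$retained,
               oracle_pdx_fp(calls, mutation_key(human)))
  expect_equal(pdx_fp_filter(calls, NULL)$retained,
               oracle_pdx_fp(calls, character(0)))
  expect_equal(indel_proximity_filter(calls)$retained,
               oracle_indel_prox(calls))
  gcalls <- random_germline_calls(1000, seed = 104)
  suppressWarnings({
    got <- germline_post_filter(gcalls, c("BRCA1", "BRCA2", "TP53"),
                                n_samples = 50)$retained
  })
  expect_equal(got, oracle_germline(gcalls, c("BRCA1", "BRCA2", "TP53"), 50))
})

test_that("retained iff failed_rules empty, and stages commute where they should", {
  calls <- random_calls(400, seed = 7, mode = "tn")
  d <- consensus_filter(calls)
  expect_equal(d$retained, d$failed_rules == "")
  # consensus and pdx-fp stages are order-independent; the indel-proximity
  # stage is not (it must see the final indel set), so it runs last
  human <- random_calls(100, seed = 8, mode = "tn")
  keep1 <- with(pdx_fp_filter(consensus_filter(calls)[
    consensus_filter(calls)$retained, ], human), key[retained])
  keep2 <- with(consensus_filter(pdx_fp_filter(calls, human)[
    pdx_fp_filter(calls, human)$retained, ]), key[retained])
  expect_setequal(keep1, keep2)
  # counterexample for indel proximity: filtering SNVs before removing a
  # low-support indel changes the outcome
  tab <- rbind(tn_call(pos = 100L),
               tn_call(pos = 110L, variant_type = "indel", callers = "pindel"))
  early <- indel_proximity_filter(tab)          # indel still present: SNV dies
  late_in <- consensus_filter(tab)
  late <- indel_proximity_filter(tab[late_in$retained, ])
  expect_false(early$retained[1])
  expect_true(late$retained[1])
})

test_that("full cohort cascade keeps lineage-true calls and drops planted FPs", {
  co <- generate_cohort(similarity_cfg(31))
  kept <- filter_cohort_mutations(co)
  # planted caller-specific false positives (single caller, 2-3 alt reads)
  # never survive
  fp_like <- kept[kept$t_alt <= 3, ]
  expect_equal(nrow(fp_like), 0)
  expect_true(all(lengths(strsplit(kept$callers, ",")) >= 2))
  # a healthy share of true clonal calls survives in every PDX sample
  pdx_ids <- co$samples$sample_id[co$samples$sample_class == "pdx"]
  expect_true(all(pdx_ids %in% kept$sample_id))
})
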