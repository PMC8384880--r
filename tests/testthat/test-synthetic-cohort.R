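test_that("sample counts follow the configured tree arithmetic", {
  cfg <- cohort_config(seed = 1, n_cases = 3, models_per_case = 2,
                       passages_per_model = 3)
  co <- generate_cohort(cfg)
  # 3 cases x (tumor + normal) + 3 x 2 models x 3 passages
  expect_equal(nrow(co$samples), 3 * 2 + 3 * 2 * 3)
  expect_equal(sum(co$samples$sample_class == "pdx"), 18)
  # invariants: passage index present iff PDX; models share their case
  expect_true(all(is.na(co$samples$passage_index) ==
                  (co$samples$sample_class != "pdx")))
  pdx <- co$samples[co$samples$sample_class == "pdx", ]
  expect_true(all(startsWith(pdx$model_id, pdx$case_id)))
  # parent links: passage 0 roots at the human tumor, later passages chain
  p0 <- pdx[pdx$passage_index == 0, ]
  expect_true(all(p0$parent_sample_id == paste0(p0$case_id, "_HT")))
  pk <- pdx[pdx$passage_index > 0, ]
  expect_true(all(pk$parent_sample_id %in% pdx$sample_id))
})

test_that("a fixed seed fixes every emitted byte", {
  cfg <- qc_cfg(42, n_loci = 200)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("mean VAF of clonal heterozygous SNVs converges to purity/2", {
  base <- list(n_cases = 1, models_per_case = 1, passages_per_model = 1,
               purity_pdx = 0.9, n_clonal_mutations = 500, n_subclones = 0,
               passage_private_mutations = 0, fp_per_sample = 0,
               indel_fraction = 0, n_snp_loci = 10, n_genes = 50,
               n_expression_groups = 1, signature_size = 2,
               segments_per_chrom = 1, n_baf_snps = 5)
  # moderate depth: within 0.02 of 0.45
  co <- generate_cohort(do.call(cohort_config,
                                c(list(seed = 5, t_depth_mean = 100), base)))
  m <- co$mutations[grepl("_P0$", co$mutations$sample_id), ]
  expect_equal(mean(m$t_alt / m$t_depth), 0.45, tolerance = 0.02 / 0.45)
  # depth 10,000: within 0.005
  co2 <- generate_cohort(do.call(cohort_config,
                                 c(list(seed = 6, t_depth_mean = 10000), base)))
  m2 <- co2$mutations[grepl("_P0$", co2$mutations$sample_id), ]
  expect_lt(abs(mean(m2$t_alt / m2$t_depth) - 0.45), 0.005)
})

test_that("P(TP53 LOH | WGD) in generated truth matches the configured rate", {
  cfg <- cn_cfg(11, n_cases = 500)
  co <- generate_cohort(cfg)
  fl <- co$truth$sample_flags
  for (wgd_state in c(TRUE, FALSE)) {
    sub <- fl[fl$wgd == wgd_state, ]
    target <- if (wgd_state) 0.9 else 0.2
    phat <- mean(sub$tp53_loh)
    half <- stats::qnorm(0.995) * sqrt(target * (1 - target) / nrow(sub))
    expect_lt(abs(phat - target), half)
  }
})

test_that("anomaly planting follows its definitions and an empty plan is identity", {
  co <- generate_cohort(qc_cfg(3, n_loci = 300))
  expect_identical(plant_anomalies(co, NULL), co)
  a <- "case001_HT"; b <- "case002_HT"
  sw <- plant_anomalies(co, data.frame(type = "swap", sample_a = a,
                                       sample_b = b, frac = NA))
  expect_equal(sw$snp$vaf[, a], co$snp$vaf[, b])
  expect_equal(sw$snp$vaf[, b], co$snp$vaf[, a])
  mix <- plant_anomalies(co, data.frame(type = "contaminate", sample_a = a,
                                        sample_b = b, frac = 0.5))
  expect_equal(mix$snp$vaf[, a], 0.5 * co$snp$vaf[, a] + 0.5 * co$snp$vaf[, b])
  expect_error(plant_anomalies(co, data.frame(type = "contaminate",
                                              sample_a = a, sample_b = b,
                                              frac = 1.2)), "strictly")
  expect_error(plant_anomalies(co, data.frame(type = "swap", sample_a = "nope",
                                              sample_b = b, frac = NA)),
               "unknown sample_id")
})

test_that("written cohorts round-trip losslessly through the readers", {
  co <- generate_cohort(qc_cfg(9, n_loci = 150))
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_equal(back$samples, co$samples)
  expect_equal(back$mutations, co$mutations)
  expect_equal(back$segments, co$segments)
  expect_equal(back$bafs, co$bafs)
  expect_equal(back$fusions, co$fusions)
  expect_equal(back$expression, co$expression)
  expect_equal(back$snp$loci, co$snp$loci)
  expect_equal(back$snp$vaf, co$snp$vaf, ignore_attr = TRUE)
  expect_equal(back$snp$depth, co$snp$depth, ignore_attr = TRUE)
  expect_equal(back$truth$sample_flags, co$truth$sample_flags)
})

test_that("cohorts with no fusions still write a header-only fusion file", {
  cfg <- qc_cfg(4, n_loci = 120)
  cfg$n_decoy_fusions <- 0L
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$fusions), 0)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  lines <- readLines(file.path(d, "fusions.tsv"))
  expect_length(lines, 1L)
  expect_match(lines, "^sample_id\t")
})

test_that("VCF positions are 1-based and segment intervals 0-based half-open", {
  skip_if_not_installed("vcfR")
  co <- generate_cohort(qc_cfg(8, n_loci = 120))
  d <- withr::local_tempdir()
  write_cohort(co, d)
  sid <- co$samples$sample_id[co$samples$sample_class == "pdx"][1]
  v <- vcfR::read.vcfR(file.path(d, "vcf", paste0(sid, ".vcf")), verbose = FALSE)
  m <- co$mutations[co$mutations$sample_id == sid, ]
  m <- m[order(match(m$chrom, names(co$config$chrom_lengths)), m$pos), ]
  expect_equal(as.integer(vcfR::getPOS(v)), m$pos)
  expect_equal(vcfR::getREF(v), m$ref)
  # conversion oracle on 100 random records: a 1-based point position maps
  # to the half-open interval [pos-1, pos) and back
  set.seed(1)
  pos <- sample(m$pos, min(100, nrow(m)), replace = TRUE)
  iv <- pos_to_interval(pos)
  expect_equal(iv$end - iv$start, rep(1, length(pos)))
  expect_equal(interval_start_to_pos(iv$start), pos)
  # segment intervals: half-open starts at 0, non-overlapping per chromosome
  segs <- co$segments
  expect_true(all(segs$start < segs$end))
  for (grp in split(segs, paste(segs$sample_id, segs$chrom))) {
    grp <- grp[order(grp$start), ]
    if (nrow(grp) > 1) expect_true(all(grp$start[-1] >= grp$end[-nrow(grp)]))
  }
  expect_true(any(segs$start == 0))
})

test_that("engraftment bottleneck makes intra-model overlap exceed inter-model", {
  wins <- 0L
  for (s in 1:20) {
    co <- generate_cohort(similarity_cfg(s))
    sets <- split(mutation_key(co$mutations),
                  co$mutations$sample_id)
    cs <- case_similarity_summary(co$mutations, co$samples)
    ok <- !is.na(cs$mean_intra) & !is.na(cs$mean_inter)
    wins <- wins + sum(cs$mean_intra[ok] > cs$mean_inter[ok])
  }
  expect_gte(wins / (20 * 2), 0.95)
})

test_that("configuration errors are rejected", {
  expect_error(cohort_config(seed = 1, n_cases = 0), "positive")
  expect_error(cohort_config(seed = 1, p_wgd = 1.4), "\\[0, 1\\]")
  expect_error(cohort_config(seed = 1, bottleneck_prob = -0.1), "\\[0, 1\\]")
  expect_error(cohort_config(), "mandatory")
  expect_error(generate_cohort(list(seed = 1)), "cohort_config")
})
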