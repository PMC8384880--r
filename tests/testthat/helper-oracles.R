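# Independent brute-force oracles, written against the rule definitions
# directly (per-row loops, no shared code with the package internals), plus
# small fixture builders.

# ---- filter-rule oracles ----------------------------------------------------

oracle_consensus <- function(calls) {
  vapply(seq_len(nrow(calls)), function(i) {
    r <- calls[i, ]
    ncall <- length(strsplit(r$callers, ",")[[1]])
    tv <- if (r$t_depth > 0) r$t_alt / r$t_depth else 0
    nv <- if (!is.na(r$n_depth) && r$n_depth > 0) r$n_alt / r$n_depth else 0
    ncall >= 2 && r$t_depth >= 14 && r$n_depth >= 8 && r$t_alt >= 4 &&
      tv >= 0.05 && nv <= 0.01
  }, TRUE)
}

oracle_tumor_only <- function(calls) {
  vapply(seq_len(nrow(calls)), function(i) {
    r <- calls[i, ]
    tv <- if (r$t_depth > 0) r$t_alt / r$t_depth else 0
    r$t_depth >= 20 && r$t_alt > 3 && tv >= 0.1
  }, TRUE)
}

oracle_pdx_fp <- function(calls, human_keys) {
  k <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  vapply(seq_len(nrow(calls)), function(i) {
    isTRUE(calls$whitelist[i]) || k[i] %in% human_keys
  }, TRUE)
}

oracle_indel_prox <- function(calls, window = 20) {
  keep <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (calls$variant_type[i] != "snv") next
    for (j in seq_len(nrow(calls))) {
      if (calls$variant_type[j] == "indel" &&
          calls$sample_id[j] == calls$sample_id[i] &&
          calls$chrom[j] == calls$chrom[i] &&
          abs(calls$pos[j] - calls$pos[i]) <= window) {
        keep[i] <- FALSE
      }
    }
  }
  keep
}

oracle_germline <- function(calls, genes, n_samples, tumor_only = FALSE,
                            somatic_keys = character(0),
                            whitelist_keys = character(0)) {
  k <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  vapply(seq_len(nrow(calls)), function(i) {
    r <- calls[i, ]
    vaf <- if (r$depth > 0) r$ad_alt / r$depth else 0
    carriers <- length(unique(calls$sample_id[k == k[i]]))
    pa <- if (is.na(r$pop_af)) 0 else r$pop_af
    ok <- r$ad_alt >= 5 && vaf >= 0.20 && carriers / n_samples <= 0.01 &&
      pa <= 0.0005 && r$gene %in% genes
    if (tumor_only) ok <- ok && !(k[i] %in% c(somatic_keys, whitelist_keys))
    ok
  }, TRUE)
}

# ---- randomized call fixtures ----------------------------------------------

random_calls <- function(n, seed, mode = c("tn", "to")) {
  mode <- match.arg(mode)
  set.seed(seed)
  caller_pool <- c("strelka", "mutect", "varscan", "pindel")
  callers <- vapply(seq_len(n), function(i) {
    paste(sort(sample(caller_pool, sample(1:4, 1))), collapse = ",")
  }, "")
  t_depth <- sample(5:40, n, TRUE)
  t_alt <- vapply(t_depth, function(d) sample(0:d, 1), 0L)
  n_depth <- sample(4:30, n, TRUE)
  n_alt <- stats::rbinom(n, n_depth, 0.03)
  df <- data.frame(
    sample_id = sample(c("s1", "s2"), n, TRUE),
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    pos = sample(1:500, n, TRUE),
    ref = sample(c("A", "C", "G", "T"), n, TRUE),
    alt = sample(c("A", "C", "G", "T"), n, TRUE),
    variant_type = sample(c("snv", "indel"), n, TRUE, prob = c(0.8, 0.2)),
    callers = callers, t_depth = t_depth, t_alt = t_alt,
    n_depth = n_depth, n_alt = n_alt,
    whitelist = stats::runif(n) < 0.3,
    stringsAsFactors = FALSE)
  if (mode == "to") { df$n_depth <- NA_integer_; df$n_alt <- NA_integer_ }
  df
}

random_germline_calls <- function(n, seed) {
  set.seed(seed)
  data.frame(
    sample_id = sample(paste0("s", 1:50), n, TRUE),
    chrom = "chr1", pos = sample(1:200, n, TRUE),
    ref = "A", alt = "G",
    gene = sample(c("BRCA1", "BRCA2", "TP53", "XYZ1", "XYZ2"), n, TRUE),
    ad_alt = sample(0:20, n, TRUE),
    depth = sample(10:40, n, TRUE),
    pop_af = ifelse(stats::runif(n) < 0.1, NA,
                    stats::runif(n, 0, 0.002)),
    stringsAsFactors = FALSE)
}

# ---- similarity / clustering / arm oracles ---------------------------------

oracle_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

oracle_shift <- function(labels) max(tabulate(match(labels, unique(labels)))) / length(labels)

# exact two-sided rank-sum p by enumeration of all group assignments
oracle_wilcox_p <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  ranks <- rank(v)
  idx <- utils::combn(length(v), n1)
  # statistic used by wilcox.test: W = ranksum(x) - n1 (n1 + 1) / 2
  ws <- apply(idx, 2, function(ii) sum(ranks[ii])) - n1 * (n1 + 1) / 2
  w_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p_lo <- mean(ws <= w_obs)
  p_hi <- mean(ws >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  exp_idx <- s(rowSums(tab)) * s(colSums(tab)) / choose(sum(tab), 2)
  (s(tab) - exp_idx) / ((s(rowSums(tab)) + s(colSums(tab))) / 2 - exp_idx)
}

# ---- small cohort configurations -------------------------------------------

# compact heterogeneity cohort: 2 models/case, model-specific bottleneck
similarity_cfg <- function(seed) {
  cohort_config(seed = seed, n_cases = 2, models_per_case = 2,
                passages_per_model = 2, n_clonal_mutations = 30,
                n_subclones = 3, subclone_mutations = 15,
                passage_private_mutations = 3, fp_per_sample = 5,
                n_snp_loci = 10, n_genes = 50, n_expression_groups = 1,
                signature_size = 2, segments_per_chrom = 1, n_baf_snps = 5)
}

# identity-QC cohort: informative SNP panel, light everything else
qc_cfg <- function(seed, n_loci = 1200) {
  cohort_config(seed = seed, n_cases = 3, models_per_case = 1,
                passages_per_model = 2, n_clonal_mutations = 5,
                n_subclones = 0, passage_private_mutations = 0,
                fp_per_sample = 0, n_snp_loci = n_loci, n_genes = 50,
                n_expression_groups = 1, signature_size = 2,
                segments_per_chrom = 1, n_baf_snps = 5)
}

# copy-number cohort: one tumor sample per case, minimal mutation load
cn_cfg <- function(seed, n_cases = 100) {
  cohort_config(seed = seed, n_cases = n_cases, models_per_case = 1,
                passages_per_model = 1, human_tumor_prob = 0,
                human_normal_prob = 0, n_clonal_mutations = 2,
                n_subclones = 0, passage_private_mutations = 0,
                fp_per_sample = 0, n_snp_loci = 10, n_genes = 50,
                n_expression_groups = 1, signature_size = 2,
                segments_per_chrom = 2, n_baf_snps = 20)
}

# expression cohort: 4 planted groups, ~30 samples per group
expression_cfg <- function(seed, group_effect = 2) {
  cohort_config(seed = seed, n_cases = 30, models_per_case = 1,
                passages_per_model = 3, human_normal_prob = 0,
                n_clonal_mutations = 5, n_subclones = 0,
                passage_private_mutations = 0, fp_per_sample = 0,
                n_snp_loci = 10, n_genes = 400, signature_size = 25,
                group_effect = group_effect, segments_per_chrom = 1,
                n_baf_snps = 5)
}
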