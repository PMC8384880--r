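test_that("variable-gene selection ranks by MAD and honors the NA rule", {
  mat <- rbind(g1 = c(0, 3, -3, 6, -6),       # largest spread
               g2 = c(0, 2, -2, 4, -4),
               g3 = c(0, 1, -1, 2, -2),
               g4 = c(5, 5, 5, 5, 5),          # constant: MAD 0
               g5 = c(7, 7, 7, 7, 7))
  expect_equal(select_variable_genes(mat, top_n = 2), c("g1", "g2"))
  # brute-force MAD oracle agrees on the full ranking
  mads <- apply(mat, 1, stats::mad)
  expect_equal(suppressWarnings(select_variable_genes(mat, top_n = 5)),
               rownames(mat)[order(-mads, rownames(mat))])
  # a gene with 40% NA is excluded regardless of MAD
  mat2 <- rbind(mat, g6 = c(100, -100, NA, NA, 0))
  expect_false("g6" %in% select_variable_genes(mat2, top_n = 3))
  # constant genes rank last, ties broken by identifier order
  sel <- suppressWarnings(select_variable_genes(mat, top_n = 5))
  expect_equal(sel[4:5], c("g4", "g5"))
  expect_warning(select_variable_genes(mat, top_n = 10), "eligible")
})

test_that("center adjustment removes constant per-center offsets", {
  set.seed(10)
  base <- matrix(rnorm(50 * 12), 50, 12,
                 dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  centers <- rep(c("A", "B"), each = 6)
  shifted <- base
  shifted[, centers == "B"] <- shifted[, centers == "B"] + 3
  adj <- center_adjust(shifted, centers)
  # the offset is removed exactly: A and B gene medians coincide
  medA <- apply(adj[, centers == "A"], 1, median)
  medB <- apply(adj[, centers == "B"], 1, median)
  expect_lt(max(abs(medA - medB)), 1e-10)
  # single center: numerically unchanged
  one <- center_adjust(base, rep("A", 12))
  expect_equal(one, base)
  expect_warning(center_adjust(base, c(rep("A", 11), "B")), "single sample")
})

test_that("consensus clustering recovers planted structure deterministically", {
  set.seed(99)
  n_per <- 15
  mat <- cbind(
    matrix(rnorm(60 * n_per, 0), 60),
    matrix(rnorm(60 * n_per, 3), 60))    # two groups, 3-SD separation
  colnames(mat) <- paste0("s", seq_len(2 * n_per))
  rownames(mat) <- paste0("g", 1:60)
  res <- consensus_cluster(mat, k_range = 2:6, iterations = 60, seed = 4)
  expect_equal(res$k, 2L)
  truth <- rep(1:2, each = n_per)
  expect_equal(adjusted_rand_index(res$assignments$group_label, truth), 1)
  # determinism under the seed
  res2 <- consensus_cluster(mat, k_range = 2:6, iterations = 60, seed = 4)
  expect_identical(res$assignments, res2$assignments)
  # consensus matrices are symmetric, unit diagonal, in [0, 1]
  for (cm in res$consensus) {
    expect_equal(cm, t(cm))
    expect_true(all(diag(cm) == 1))
    expect_true(all(cm >= 0 & cm <= 1))
  }
  # samples always co-clustered have consensus 1 within a group
  cm2 <- res$consensus[["2"]]
  expect_equal(unname(cm2[1, 2]), 1)
  # appending duplicates keeps them co-assigned with their originals
  dup <- cbind(mat, mat[, 1:4])
  colnames(dup) <- c(colnames(mat), paste0("dup", 1:4))
  resd <- consensus_cluster(dup, k_range = 2:4, iterations = 60, seed = 5)
  lab <- stats::setNames(resd$assignments$group_label,
                         resd$assignments$sample_id)
  expect_equal(unname(lab[paste0("dup", 1:4)]), unname(lab[paste0("s", 1:4)]))
  expect_error(consensus_cluster(mat, k_range = 2:40, seed = 1), "k_range")
  # manual override wins over the elbow
  reso <- consensus_cluster(mat, k_range = 2:4, iterations = 30, seed = 6,
                            k_override = 3)
  expect_equal(reso$k, 3L)
})

test_that("group DEGs use one-vs-rest Wilcoxon with BH and positive fold change", {
  set.seed(12)
  mat <- rbind(up = c(rnorm(10, 10), rnorm(30, 2)),
               flat = rnorm(40, 5),
               t(matrix(rnorm(40 * 20, 5), ncol = 20)))
  rownames(mat) <- c("up", "flat", paste0("bg", 1:20))
  colnames(mat) <- paste0("s", 1:40)
  asg <- data.frame(sample_id = colnames(mat),
                    group_label = rep(c(1L, 2L), c(10, 30)))
  degs <- group_degs(mat, asg)
  hit <- degs[degs$group_label == 1 & degs$gene == "up", ]
  expect_equal(nrow(hit), 1)
  expect_lt(hit$p, 1e-6)
  expect_false("flat" %in% degs$gene[degs$group_label == 1])
  # groups below 3 samples are skipped with a warning
  asg2 <- asg; asg2$group_label[1:38] <- 1L; asg2$group_label[39:40] <- 2L
  expect_warning(group_degs(mat, asg2), "fewer than 3")
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), method = "BH"),
               c(0.03, 0.03, 0.04))
  set.seed(31)
  for (i in 1:50) {
    p <- stats::runif(sample(3:20, 1))
    expect_equal(stats::p.adjust(p, method = "BH"), oracle_bh(p))
  }
})

test_that("cluster shift score is the maximum group fraction", {
  expect_equal(cluster_shift_score(c(1, 1, 1))$score, 1.0)
  expect_equal(cluster_shift_score(c(1, 1, 2, 2))$score, 0.5)
  expect_equal(cluster_shift_score(c(1, 2, 3, 4))$score, 0.25)
  # brute-force definition check over random label vectors, and the
  # score-1 iff all-co-assigned equivalence
  set.seed(14)
  for (i in 1:500) {
    l <- sample(1:4, sample(1:8, 1), replace = TRUE)
    s <- cluster_shift_score(l)$score
    expect_equal(s, oracle_shift(l))
    expect_equal(s == 1, length(unique(l)) == 1L)
  }
})

test_that("cis/trans testing excludes silent mutations and finds planted effects", {
  set.seed(16)
  n_mut <- 15; n_wt <- 30
  ids <- paste0("s", seq_len(n_mut + n_wt))
  mat <- matrix(rnorm(30 * (n_mut + n_wt), 5), 30,
                dimnames = list(c("QUERY", paste0("t", 1:29)), ids))
  mat["QUERY", seq_len(n_mut)] <- mat["QUERY", seq_len(n_mut)] - 2  # cis down
  calls <- data.frame(sample_id = ids[seq_len(n_mut)], gene = "QUERY",
                      effect = "non_silent")
  res <- cis_trans_test(mat, calls, "QUERY")
  cis <- res[res$relation == "cis", ]
  expect_equal(cis$gene, "QUERY")
  expect_equal(cis$direction, "down")
  expect_true(cis$significant)
  expect_true(cis$fdr < 0.1)
  # a sample whose only mutation in the gene is silent counts as wild-type
  calls2 <- rbind(calls, data.frame(sample_id = ids[n_mut + 1],
                                    gene = "QUERY", effect = "silent"))
  res2 <- cis_trans_test(mat, calls2, "QUERY")
  expect_equal(res2$n_mut[1], n_mut)
  # below-minimum group: not testable
  expect_warning(out <- cis_trans_test(mat, calls[1:2, ], "QUERY"),
                 "minimum")
  expect_null(out)
})

test_that("permuted mutation labels yield a calibrated (empty) cis/trans null", {
  set.seed(18)
  ids <- paste0("s", 1:40)
  mat <- matrix(rnorm(25 * 40, 5), 25,
                dimnames = list(paste0("g", 1:25), ids))
  n_sig <- 0
  for (i in 1:60) {
    mut <- sample(ids, 12)
    calls <- data.frame(sample_id = mut, gene = "g1", effect = "non_silent")
    res <- cis_trans_test(mat, calls, "g1")
    n_sig <- n_sig + sum(res$significant)
  }
  expect_lte(n_sig / (60 * 25), 0.01)
})
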