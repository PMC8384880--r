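#' Select the most variable genes by median absolute deviation
#'
#' Drops genes with an NA fraction of 0.30 or more, ranks the rest by MAD
#' across samples (NA-ignoring), and returns the `top_n` genes, ties broken
#' by gene identifier order.
#'
#' @param mat genes x samples numeric matrix with rownames.
#' @param top_n number of genes to keep (default 1000).
#' @param max_na_fraction exclusive NA-fraction bound (default 0.30).
#' @return character vector of selected gene identifiers. Fewer than `top_n`
#'   eligible genes returns all of them with a warning.
#' @export
select_variable_genes <- function(mat, top_n = 1000, max_na_fraction = 0.30) {
  stopifnot(nrow(mat) > 0)
  na_frac <- rowMeans(is.na(mat))
  eligible <- which(na_frac < max_na_fraction)
  mads <- apply(mat[eligible, , drop = FALSE], 1L, stats::mad, na.rm = TRUE)
  ids <- rownames(mat)[eligible]
  ord <- order(-mads, ids)
  if (length(eligible) < top_n) {
    warning(sprintf("only %d eligible genes (requested %d)",
                    length(eligible), top_n))
    return(ids[ord])
  }
  ids[ord][seq_len(top_n)]
}

#' Remove per-center offsets from an expression matrix
#'
#' Stand-in batch adjustment: per gene, each center's median is subtracted
#' and the global gene median restored, which removes constant per-center
#' offsets exactly. Centers with a single sample are passed through
#' unchanged with a warning. Pipelines with a dedicated batch-correction
#' step can supply an externally adjusted matrix instead.
#'
#' @param mat genes x samples matrix.
#' @param centers center label per column of `mat`.
#' @return adjusted matrix of the same shape.
#' @export
center_adjust <- function(mat, centers) {
  stopifnot(length(centers) == ncol(mat))
  out <- mat
  gmed <- apply(mat, 1L, stats::median, na.rm = TRUE)
  for (cen in unique(centers)) {
    sel <- centers == cen
    if (sum(sel) < 2L) {
      warning(sprintf("center '%s' has a single sample; passed through", cen))
      next
    }
    cmed <- apply(mat[, sel, drop = FALSE], 1L, stats::median, na.rm = TRUE)
    out[, sel] <- mat[, sel, drop = FALSE] - cmed + gmed
  }
  out
}

#' Consensus clustering of samples with automatic k selection
#'
#' Genes are scaled across samples (zero center, unit spread), then for each
#' candidate k the samples are repeatedly subsampled and partitioned with a
#' k-means base partitioner; co-assignment frequencies among co-subsampled
#' pairs form the consensus matrix. Final labels come from average-linkage
#' hierarchical clustering of 1 - consensus. k is selected from the shape of
#' the consensus CDFs: the proportion of ambiguous clustering (PAC: the mass
#' of consensus entries strictly between `pac_bounds`) is minimized, with
#' ties broken toward the smallest k; the classical delta-area curve is
#' reported alongside, and `k_override` fixes k manually. PAC is used
#' because with a k-means base partitioner, splits beyond the true k are
#' arbitrary yet keep inflating the delta-area, while they visibly smear
#' the consensus distribution that PAC measures.
#'
#' @param mat genes x samples matrix (typically the variable-gene subset).
#' @param k_range candidate cluster counts (default 2:6).
#' @param iterations subsample iterations per k (default 1000).
#' @param subsample_fraction fraction of samples per iteration (default 0.8).
#' @param seed RNG seed; results are deterministic given it.
#' @param pac_bounds ambiguity band for the PAC criterion.
#' @param k_override fix k manually instead of the PAC choice.
#' @param nstart k-means restarts per iteration.
#' @return list with `assignments` (data frame `sample_id`, `group_label`,
#'   `confidence`), `k`, `consensus` (list of matrices, one per k), `pac`,
#'   and `delta_area`.
#' @export
consensus_cluster <- function(mat, k_range = 2:6, iterations = 1000,
                              subsample_fraction = 0.8, seed = 1,
                              pac_bounds = c(0.1, 0.9), k_override = NULL,
                              nstart = 3) {
  n <- ncol(mat)
  if (any(k_range >= n)) stop("k_range contains k >= number of samples",
                              call. = FALSE)
  x <- t(scale(t(mat)))            # scale each gene across samples
  x <- x[stats::complete.cases(x), , drop = FALSE]
  xs <- t(x)                        # samples x genes for kmeans
  m_sub <- max(2L, floor(subsample_fraction * n))
  with_seed(seed, {
    consensus <- list()
    for (k in k_range) {
      co <- matrix(0, n, n)
      cnt <- matrix(0, n, n)
      for (it in seq_len(iterations)) {
        idx <- sample.int(n, m_sub)
        cl <- stats::kmeans(xs[idx, , drop = FALSE], centers = k,
                            nstart = nstart, iter.max = 30)$cluster
        same <- outer(cl, cl, "==") * 1
        co[idx, idx] <- co[idx, idx] + same
        cnt[idx, idx] <- cnt[idx, idx] + 1
      }
      cons <- ifelse(cnt > 0, co / pmax(cnt, 1), 0)
      diag(cons) <- 1
      dimnames(cons) <- list(colnames(mat), colnames(mat))
      consensus[[as.character(k)]] <- cons
    }
    area <- vapply(consensus, consensus_cdf_area, 0)
    delta <- numeric(length(area))
    delta[1] <- area[1]
    if (length(area) > 1L) {
      delta[-1] <- diff(area) / pmax(area[-length(area)], .Machine$double.eps)
    }
    names(delta) <- names(area)
    pac <- vapply(consensus, function(cm) {
      v <- cm[upper.tri(cm)]
      mean(v > pac_bounds[1] & v < pac_bounds[2])
    }, 0)
    k <- if (!is.null(k_override)) k_override else
      k_range[which.min(pac)]
    cons <- consensus[[as.character(k)]]
    hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
    labels <- stats::cutree(hc, k = k)
    confidence <- vapply(seq_len(n), function(i) {
      mates <- which(labels == labels[i])
      mates <- setdiff(mates, i)
      if (length(mates) == 0L) 1 else mean(cons[i, mates])
    }, 0)
    list(assignments = data.frame(sample_id = colnames(mat),
                                  group_label = as.integer(labels),
                                  confidence = confidence,
                                  stringsAsFactors = FALSE),
         k = as.integer(k), consensus = consensus, pac = pac,
         delta_area = delta)
  })
}

# area under the empirical CDF of the upper-triangular consensus entries
consensus_cdf_area <- function(cons) {
  v <- sort(cons[upper.tri(cons)])
  if (length(v) == 0L) return(0)
  cdf <- stats::ecdf(v)
  grid <- seq(0, 1, length.out = 101)
  sum(diff(grid) * cdf(grid[-length(grid)]))
}

#' Differentially expressed genes per transcriptional group
#'
#' One-vs-rest two-sided Wilcoxon rank-sum test per gene, Benjamini-Hochberg
#' adjusted across genes within each comparison; reported genes pass the FDR
#' cutoff with positive fold change (group mean / rest mean on the supplied
#' expression scale). Groups smaller than 3 samples are skipped with a
#' warning.
#'
#' @param mat genes x samples matrix.
#' @param assignments data frame `(sample_id, group_label)`.
#' @param fdr_cutoff BH-FDR threshold (default 0.05).
#' @param fold_change_min minimum group/rest mean ratio (default 1).
#' @return data frame `(group_label, gene, p, fdr, fold_change)` of reported
#'   genes.
#' @export
group_degs <- function(mat, assignments, fdr_cutoff = 0.05,
                       fold_change_min = 1) {
  groups <- sort(unique(assignments$group_label))
  stopifnot(length(groups) >= 2L)
  lab <- assignments$group_label[match(colnames(mat), assignments$sample_id)]
  rows <- list()
  for (g in groups) {
    sel <- lab == g
    if (sum(sel) < 3L) {
      warning(sprintf("group %s has fewer than 3 samples; skipped", g))
      next
    }
    p <- apply(mat, 1L, function(v) {
      a <- v[sel]; b <- v[!sel]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2L || length(b) < 2L) return(NA_real_)
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    })
    fc <- rowMeans(mat[, sel, drop = FALSE], na.rm = TRUE) /
      rowMeans(mat[, !sel, drop = FALSE], na.rm = TRUE)
    fdr <- stats::p.adjust(p, method = "BH")
    hit <- which(!is.na(fdr) & fdr < fdr_cutoff & fc > fold_change_min)
    if (length(hit) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        group_label = g, gene = rownames(mat)[hit], p = p[hit], fdr = fdr[hit],
        fold_change = fc[hit], row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(group_label = integer(), gene = character(),
                      p = numeric(), fdr = numeric(), fold_change = numeric()))
  }
  do.call(rbind, rows)
}

#' Cluster shift score of a PDX model
#'
#' The largest fraction of a model's samples assigned to a single
#' transcriptional group: 1 means all samples co-assign (a perfectly stable
#' model), lower values mean the model's expression profile shifts across
#' passages.
#'
#' @param labels group labels of one model's samples (length >= 1).
#' @return list `(n_samples, score)`.
#' @export
cluster_shift_score <- function(labels) {
  stopifnot(length(labels) >= 1L)
  list(n_samples = length(labels),
       score = max(table(labels)) / length(labels))
}

#' Cluster shift scores for every model
#'
#' @param assignments data frame `(sample_id, group_label)`.
#' @param samples sample metadata with `sample_id` and `model_id`.
#' @return data frame `(model_id, n_samples, score)`.
#' @export
model_shift_scores <- function(assignments, samples) {
  model_of <- stats::setNames(samples$model_id, samples$sample_id)
  a <- assignments[!is.na(model_of[assignments$sample_id]), , drop = FALSE]
  rows <- lapply(split(a$group_label, model_of[a$sample_id]), function(l) {
    s <- cluster_shift_score(l)
    data.frame(n_samples = s$n_samples, score = s$score)
  })
  out <- do.call(rbind, rows)
  data.frame(model_id = names(rows), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Cis and trans effects of a mutated gene on expression
#'
#' Samples are split into mutated and wild-type groups by non-silent
#' mutation status in the query gene (samples whose only mutations in the
#' gene are silent count as wild-type). A two-sided Wilcoxon rank-sum test
#' compares expression of each target gene between the groups; BH-FDR is
#' applied across targets, and effects with FDR below the cutoff are
#' reported with direction. The target equal to the query gene is the cis
#' effect; all others are trans.
#'
#' @param mat genes x samples expression matrix.
#' @param calls filtered mutation calls (`sample_id`, `gene`, `effect`).
#' @param query_gene mutated gene defining the groups.
#' @param target_genes genes to test (default: all rows of `mat`).
#' @param fdr_cutoff reporting threshold (default 0.1).
#' @param min_group minimum size of each group (default 3).
#' @return data frame `(gene, relation, n_mut, n_wt, direction, p, fdr,
#'   significant)`; `NULL` when a group is below `min_group`.
#' @export
cis_trans_test <- function(mat, calls, query_gene,
                           target_genes = rownames(mat),
                           fdr_cutoff = 0.1, min_group = 3) {
  mut_samples <- unique(calls$sample_id[calls$gene == query_gene &
                                        calls$effect != "silent"])
  ids <- colnames(mat)
  mutated <- ids %in% mut_samples
  if (sum(mutated) < min_group || sum(!mutated) < min_group) {
    warning("mutated or wild-type group below minimum size; not testable")
    return(NULL)
  }
  target_genes <- intersect(target_genes, rownames(mat))
  p <- vapply(target_genes, function(g) {
    a <- mat[g, mutated]; b <- mat[g, !mutated]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) return(NA_real_)
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }, 0)
  dirn <- vapply(target_genes, function(g) {
    d <- stats::median(mat[g, mutated], na.rm = TRUE) -
      stats::median(mat[g, !mutated], na.rm = TRUE)
    if (is.na(d)) NA_character_ else if (d >= 0) "up" else "down"
  }, "")
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(gene = target_genes,
             relation = ifelse(target_genes == query_gene, "cis", "trans"),
             n_mut = sum(mutated), n_wt = sum(!mutated),
             direction = dirn, p = p, fdr = fdr,
             significant = !is.na(fdr) & fdr < fdr_cutoff,
             row.names = NULL, stringsAsFactors = FALSE)
}
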