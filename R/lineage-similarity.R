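#' Mutational similarity between two mutation sets
#'
#' The fraction of overlapping mutations between two samples, computed on
#' canonical (chrom, pos, ref, alt) keys. The default is the Jaccard index
#' |A intersect B| / |A union B|; the overlap coefficient |A intersect B| /
#' min(|A|, |B|) is available as an alternative convention. Two empty sets
#' are defined as similarity 1 (vacuous agreement) and carry a `vacuous`
#' attribute so callers can exclude them; exactly one empty set gives 0.
#'
#' @param set_a,set_b character vectors of mutation keys (duplicates are
#'   collapsed).
#' @param method `"jaccard"` (default) or `"overlap"`.
#' @return similarity in [0, 1].
#' @export
mutational_similarity <- function(set_a, set_b, method = c("jaccard", "overlap")) {
  method <- match.arg(method)
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) == 0L && length(b) == 0L) {
    return(structure(1, vacuous = TRUE))
  }
  ni <- length(intersect(a, b))
  denom <- switch(method,
                  jaccard = length(a) + length(b) - ni,
                  overlap = min(length(a), length(b)))
  ni / denom
}

# mutation key sets per sample from a filtered calls table
sample_key_sets <- function(calls, scope = c("all_mutations", "driver_only")) {
  scope <- match.arg(scope)
  if (scope == "driver_only") calls <- calls[calls$driver %in% TRUE, , drop = FALSE]
  split(mutation_key(calls), calls$sample_id)
}

#' Pairwise similarity matrix with lineage relation labels
#'
#' @param calls filtered mutation calls (must contain `sample_id` and the
#'   key columns).
#' @param samples sample metadata (`sample_id`, `case_id`, `model_id`,
#'   `sample_class`).
#' @param scope `"all_mutations"` or `"driver_only"`.
#' @param method see [mutational_similarity()].
#' @return list with the symmetric numeric `matrix` (unit diagonal for
#'   non-empty sets) and a long data frame `pairs` with columns
#'   `sample_id_a`, `sample_id_b`, `similarity`, `relation`
#'   (`intra_model` / `inter_model` / `human_vs_pdx` / `other`).
#' @export
similarity_matrix <- function(calls, samples,
                              scope = c("all_mutations", "driver_only"),
                              method = "jaccard") {
  scope <- match.arg(scope)
  sets <- sample_key_sets(calls, scope)
  ids <- intersect(samples$sample_id, names(sets))
  empty <- setdiff(samples$sample_id[samples$sample_class != "human_normal"],
                   names(sets))
  ids <- c(ids, empty)
  sets[empty] <- list(character(0))
  n <- length(ids)
  m <- matrix(1, n, n, dimnames = list(ids, ids))
  meta <- samples[match(ids, samples$sample_id), ]
  rows <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
      s <- mutational_similarity(sets[[ids[i]]], sets[[ids[j]]], method)
      m[i, j] <- m[j, i] <- as.numeric(s)
      rel <- if (meta$sample_class[i] == "pdx" && meta$sample_class[j] == "pdx") {
        if (identical(meta$case_id[i], meta$case_id[j])) {
          if (identical(meta$model_id[i], meta$model_id[j])) "intra_model"
          else "inter_model"
        } else "other"
      } else if (xor(meta$sample_class[i] == "human_tumor",
                     meta$sample_class[j] == "human_tumor") &&
                 identical(meta$case_id[i], meta$case_id[j]) &&
                 "pdx" %in% c(meta$sample_class[i], meta$sample_class[j])) {
        "human_vs_pdx"
      } else "other"
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id_a = ids[i], sample_id_b = ids[j],
        similarity = as.numeric(s), relation = rel, stringsAsFactors = FALSE)
    }
  }
  list(matrix = m,
       pairs = if (length(rows)) do.call(rbind, rows) else
         data.frame(sample_id_a = character(), sample_id_b = character(),
                    similarity = numeric(), relation = character()))
}

#' Per-case intra- vs inter-model similarity summary
#'
#' Intra pairs are PDX samples sharing a model; inter pairs are PDX samples
#' of the same case from different models. Cases without eligible pairs are
#' reported with `NA` (absent), never 0.
#'
#' @inheritParams similarity_matrix
#' @return data frame `(case_id, n_pdx, mean_intra, mean_inter)`.
#' @export
case_similarity_summary <- function(calls, samples,
                                    scope = c("all_mutations", "driver_only"),
                                    method = "jaccard") {
  sm <- similarity_matrix(calls, samples, scope, method)
  p <- sm$pairs
  case_of <- stats::setNames(samples$case_id, samples$sample_id)
  p$case_id <- case_of[p$sample_id_a]
  rows <- lapply(unique(samples$case_id), function(cid) {
    sub <- p[p$case_id %in% cid, , drop = FALSE]
    intra <- sub$similarity[sub$relation == "intra_model"]
    inter <- sub$similarity[sub$relation == "inter_model"]
    data.frame(case_id = cid,
               n_pdx = sum(samples$case_id == cid & samples$sample_class == "pdx"),
               mean_intra = if (length(intra)) mean(intra) else NA_real_,
               mean_inter = if (length(inter)) mean(inter) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Human-tumor vs PDX similarity per model
#'
#' For each PDX model with a matched human tumor, reports the similarity of
#' each passage's mutation set to the human tumor's, summarizes the model by
#' the median across passages, and flags models whose score falls below 0.2
#' (the regime in which subclonal selection or low purity has washed out most
#' of the human tumor's mutations).
#'
#' @inheritParams similarity_matrix
#' @param flag_below low-similarity threshold (default 0.2).
#' @return data frame `(model_id, case_id, n_passages, score,
#'   low_similarity)`; models without a matched human tumor are omitted.
#' @export
human_pdx_similarity <- function(calls, samples, scope = "all_mutations",
                                 method = "jaccard", flag_below = 0.2) {
  sets <- sample_key_sets(calls, scope)
  rows <- list()
  for (mid in unique(stats::na.omit(samples$model_id))) {
    ms <- samples[samples$model_id %in% mid, , drop = FALSE]
    cid <- ms$case_id[1]
    ht <- samples$sample_id[samples$case_id == cid &
                            samples$sample_class == "human_tumor"]
    if (length(ht) == 0L) next
    hset <- sets[[ht[1]]] %||% character(0)
    if (length(hset) == 0L) next
    per_pass <- vapply(ms$sample_id, function(sid) {
      as.numeric(mutational_similarity(hset, sets[[sid]] %||% character(0), method))
    }, 0)
    score <- stats::median(per_pass)
    rows[[length(rows) + 1L]] <- data.frame(
      model_id = mid, case_id = cid, n_passages = nrow(ms), score = score,
      low_similarity = score < flag_below, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(model_id = character(), case_id = character(),
                      n_passages = integer(), score = numeric(),
                      low_similarity = logical()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
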