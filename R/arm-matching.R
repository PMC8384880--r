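#' Treatment-arm eligibility rules
#'
#' Arm rules are data, not code: each rule names a drug, one or more
#' inclusion criteria (gene set + alteration class, optionally an exact
#' variant list), disease exclusions (cancer-type codes), and optional
#' biomarker requirements. `example_arm_rules()` ships a small illustrative
#' set modeled on well-known basket-trial gene/drug pairs; real trial
#' criteria are user-supplied at the same interface.
#'
#' @return list of arm-rule lists.
#' @export
example_arm_rules <- function() {
  list(
    list(arm_id = "ARM-PIK3CA", drug = "copanlisib",
         inclusion = list(list(genes = "PIK3CA", class = "non_silent_mutation")),
         exclusions = character(0), biomarkers = list()),
    list(arm_id = "ARM-BRAF", drug = "dabrafenib+trametinib",
         inclusion = list(list(genes = "BRAF", class = "variant_whitelist",
                               variants = "V600E")),
         exclusions = c("COAD", "READ"), biomarkers = list()),
    list(arm_id = "ARM-ERBB2", drug = "trastuzumab+pertuzumab",
         inclusion = list(list(genes = "ERBB2", class = "amplification")),
         exclusions = character(0), biomarkers = list()),
    list(arm_id = "ARM-CCND1", drug = "palbociclib",
         inclusion = list(list(genes = "CCND1", class = "amplification")),
         exclusions = character(0), biomarkers = list()),
    list(arm_id = "ARM-PTEN", drug = "GSK2636771",
         inclusion = list(list(genes = "PTEN", class = "deletion")),
         exclusions = character(0), biomarkers = list()),
    list(arm_id = "ARM-FGFR", drug = "erdafitinib",
         inclusion = list(list(genes = c("FGFR1", "FGFR2", "FGFR3"),
                               class = "non_silent_mutation"),
                          list(genes = c("FGFR1", "FGFR2", "FGFR3"),
                               class = "fusion")),
         exclusions = character(0), biomarkers = list()))
}

#' @rdname example_arm_rules
#' @param path JSON file of arm rules.
#' @export
read_arm_rules <- function(path) {
  rules <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  for (r in rules) {
    if (is.null(r$arm_id) || length(r$inclusion) < 1L) {
      stop("each arm rule needs an arm_id and at least one inclusion criterion",
           call. = FALSE)
    }
  }
  rules
}

#' @rdname example_arm_rules
#' @param rules list of arm rules to serialize.
#' @export
write_arm_rules <- function(rules, path) {
  jsonlite::write_json(rules, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Gene-level copy-number category from segments
#'
#' Assigns each gene the category of the retained segment overlapping it the
#' most (genes with no overlapping segment are omitted).
#'
#' @param segments retained SEG-like segments (one or more samples).
#' @param genes gene annotation (`gene`, `chrom`, `start`, `end`), default
#'   [pdx_gene_table()].
#' @return data frame `(sample_id, gene, cn_category)`.
#' @export
gene_cn_category <- function(segments, genes = pdx_gene_table()) {
  segments$category <- call_cn_category(segments$log2)
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    hit <- segments[segments$chrom == g$chrom & segments$start < g$end &
                    segments$end > g$start, , drop = FALSE]
    if (nrow(hit) == 0L) next
    ov <- pmin(hit$end, g$end) - pmax(hit$start, g$start)
    best <- vapply(split(seq_len(nrow(hit)), hit$sample_id),
                   function(idx) idx[which.max(ov[idx])], 0L)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = names(best), gene = g$gene,
      cn_category = hit$category[best], row.names = NULL,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample_id = character(), gene = character(),
                      cn_category = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Normalized alteration table for arm matching
#'
#' Collapses filtered mutation calls, gene-level copy-number categories, and
#' post-filter fusion records into long-format alterations
#' `(sample_id, gene, class, variant)` — the input unit of
#' [match_alterations_to_arms()].
#'
#' @param calls filtered mutation calls (`sample_id`, `gene`, `effect`,
#'   `hotspot`).
#' @param gene_cn output of [gene_cn_category()] (optional).
#' @param fusions fusion records already past [kinase_fusion_classify()]'s
#'   keep decision (optional).
#' @return alteration data frame.
#' @export
sample_alterations <- function(calls = NULL, gene_cn = NULL, fusions = NULL) {
  rows <- list()
  if (!is.null(calls) && nrow(calls) > 0L) {
    ns <- calls[calls$effect == "non_silent", , drop = FALSE]
    if (nrow(ns) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = ns$sample_id, gene = ns$gene, class = "non_silent_mutation",
        variant = if ("hotspot" %in% names(ns)) ns$hotspot else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(gene_cn) && nrow(gene_cn) > 0L) {
    cn <- gene_cn[gene_cn$cn_category %in% c("amplification", "deletion"), ,
                  drop = FALSE]
    if (nrow(cn) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = cn$sample_id, gene = cn$gene, class = cn$cn_category,
        variant = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(fusions) && nrow(fusions) > 0L) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = rep(fusions$sample_id, 2L),
      gene = c(fusions$gene5, fusions$gene3), class = "fusion",
      variant = NA_character_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample_id = character(), gene = character(),
                      class = character(), variant = character(),
                      stringsAsFactors = FALSE)
  }
  unique(out)
}

criterion_matches <- function(alts, crit) {
  cls <- crit$class
  if (cls == "non_silent_mutation") {
    alts$class == "non_silent_mutation" & alts$gene %in% crit$genes
  } else if (cls == "variant_whitelist") {
    alts$class == "non_silent_mutation" & alts$gene %in% crit$genes &
      !is.na(alts$variant) & alts$variant %in% crit$variants
  } else if (cls %in% c("amplification", "deletion")) {
    alts$class == cls & alts$gene %in% crit$genes
  } else if (cls == "fusion") {
    alts$class == "fusion" & alts$gene %in% crit$genes
  } else stop(sprintf("unknown criterion class '%s'", cls), call. = FALSE)
}

#' Match one unit's alterations against arm rules
#'
#' A unit (sample or model) matches an arm iff at least one inclusion
#' criterion matches, its cancer type is not excluded, and all biomarker
#' requirements hold. A missing cancer type is passed through with a warning
#' (exclusions then cannot fire).
#'
#' @param alts alteration table of one unit ([sample_alterations()]).
#' @param cancer_type the unit's cancer-type code.
#' @param rules list of arm rules.
#' @param biomarkers named list of the unit's biomarker values.
#' @return data frame `(arm_id, drug, n_alterations, alteration_keys)` of
#'   matched arms.
#' @export
match_alterations_to_arms <- function(alts, cancer_type, rules,
                                      biomarkers = list()) {
  if (is.null(cancer_type) || is.na(cancer_type) || cancer_type == "") {
    warning("unknown cancer type; disease exclusions cannot be applied")
    cancer_type <- NA_character_
  }
  rows <- list()
  for (r in rules) {
    if (!is.na(cancer_type) && cancer_type %in% r$exclusions) next
    bm <- r$biomarkers %||% list()
    if (length(bm) > 0L) {
      ok <- all(vapply(names(bm), function(k) {
        identical(biomarkers[[k]], bm[[k]])
      }, TRUE))
      if (!ok) next
    }
    hit <- Reduce(`|`, lapply(r$inclusion, function(cr) {
      criterion_matches(alts, cr)
    }), accumulate = FALSE)
    if (length(hit) > 0L && any(hit)) {
      keys <- unique(paste0(alts$gene[hit], ":", alts$class[hit]))
      rows[[length(rows) + 1L]] <- data.frame(
        arm_id = r$arm_id, drug = r$drug %||% NA_character_,
        n_alterations = sum(hit),
        alteration_keys = paste(sort(keys), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(arm_id = character(), drug = character(),
                      n_alterations = integer(), alteration_keys = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Classify models by matched-arm count
#'
#' @param matches data frame with `model_id` and `arm_id` (model-level).
#' @param model_ids all model identifiers in the cohort.
#' @return list `(single_arm, multi_arm, unmatched)` of model-id vectors.
#' @export
classify_models <- function(matches, model_ids) {
  counts <- vapply(model_ids, function(m) {
    length(unique(matches$arm_id[matches$model_id == m]))
  }, 0L)
  list(single_arm = model_ids[counts == 1L],
       multi_arm = model_ids[counts >= 2L],
       unmatched = model_ids[counts == 0L])
}

#' Passage-depth score of an arm
#'
#' Bins the PDX samples of the models matching an arm by passage index;
#' `N_pb` is the number of distinct passage bins and a bin is positive when
#' at least one PDX sample with that passage index is itself
#' target-positive (per-sample re-detection). `S_arm` is the fraction of
#' positive bins; `S_arm = 1` means every represented passage bin carries a
#' positive sample. Set `cohort_bins = TRUE` to bin over all PDX samples of
#' the cohort instead of only the matched models'.
#'
#' @param positive_samples sample ids that are target-positive for the arm.
#' @param matched_models model ids matching the arm (model level).
#' @param samples sample metadata (`sample_id`, `model_id`, `sample_class`,
#'   `passage_index`).
#' @param cohort_bins use cohort-wide passage bins.
#' @return list `(s_arm, n_pb, positive_bins)`; `NULL` when no PDX samples
#'   define bins (undefined score).
#' @export
s_arm_score <- function(positive_samples, matched_models, samples,
                        cohort_bins = FALSE) {
  pdx <- samples[samples$sample_class == "pdx", , drop = FALSE]
  rel <- if (cohort_bins) pdx else
    pdx[pdx$model_id %in% matched_models, , drop = FALSE]
  bins <- sort(unique(rel$passage_index))
  if (length(bins) == 0L) return(NULL)
  pos_pass <- pdx$passage_index[pdx$sample_id %in% positive_samples]
  positive_bins <- bins %in% pos_pass
  list(s_arm = sum(positive_bins) / length(bins),
       n_pb = length(bins),
       positive_bins = stats::setNames(positive_bins, bins))
}

#' Classify kinase fusions and apply the abundance filter
#'
#' Labels each fusion by which partner is a kinase (5', 3', both, none) and
#' decides retention: fusions carrying any normal-panel annotation tag or
#' with FFPM at or below 0.1 are dropped.
#'
#' @param fusions fusion records (`gene5`, `gene3`, `ffpm`,
#'   `annotation_tags` as comma-separated string).
#' @param kinase_genes character vector of kinase gene symbols.
#' @param min_ffpm strict FFPM retention bound (default 0.1).
#' @return the fusions with `kinase_class` and `keep` columns.
#' @export
kinase_fusion_classify <- function(fusions, kinase_genes, min_ffpm = 0.1) {
  k5 <- fusions$gene5 %in% kinase_genes
  k3 <- fusions$gene3 %in% kinase_genes
  fusions$kinase_class <- ifelse(k5 & k3, "both",
                          ifelse(k5, "five_prime",
                          ifelse(k3, "three_prime", "none")))
  tagged <- !is.na(fusions$annotation_tags) & fusions$annotation_tags != ""
  fusions$keep <- fusions$ffpm > min_ffpm & !tagged
  fusions
}

#' Alteration-expression association for a target gene
#'
#' Two-sided Wilcoxon rank-sum test of the target gene's expression between
#' altered and wild-type groups; the association passes when p < 0.05 and
#' |log2 fold change of group means| > 0.585.
#'
#' @param expr_values named expression vector of the target gene.
#' @param altered logical vector (same order) marking the altered group.
#' @param p_cutoff,lfc_cutoff pass thresholds.
#' @return list `(log2_fc, p_value, pass)`; `NULL` when a group is empty.
#' @export
alteration_expression_association <- function(expr_values, altered,
                                              p_cutoff = 0.05,
                                              lfc_cutoff = 0.585) {
  ok <- !is.na(expr_values) & !is.na(altered)
  x <- expr_values[ok & altered]
  y <- expr_values[ok & !altered]
  if (length(x) == 0L || length(y) == 0L) return(NULL)
  lfc <- log2(mean(x) / mean(y))
  p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
  list(log2_fc = lfc, p_value = p,
       pass = is.finite(lfc) && !is.na(p) && p < p_cutoff &&
         abs(lfc) > lfc_cutoff)
}

#' End-to-end arm matching on a cohort
#'
#' Runs the full chain: somatic filter cascade, gene-level copy number from
#' quality-filtered segments, fusion filtering, per-sample alteration
#' assembly, per-sample and model-level arm matching, model classification,
#' and per-arm passage-depth scores.
#'
#' @param cohort a `pdx_cohort`.
#' @param rules arm rules (default [example_arm_rules()]).
#' @param kinase_genes kinase symbols for fusion classification.
#' @return list `(sample_matches, model_matches, classification, arm_scores,
#'   alterations)`.
#' @export
cohort_arm_matching <- function(cohort, rules = example_arm_rules(),
                                kinase_genes = c("FGFR1", "FGFR2", "FGFR3",
                                                 "BRAF", "EGFR", "MET",
                                                 "CDK6", "KIT", "AKT1")) {
  kept <- filter_cohort_mutations(cohort)
  segs <- segment_quality_filter(cohort$segments)
  gcn <- gene_cn_category(segs)
  fus <- kinase_fusion_classify(cohort$fusions, kinase_genes)
  fus <- fus[fus$keep, , drop = FALSE]
  alts <- sample_alterations(kept, gcn, fus)
  pdx <- cohort$samples[cohort$samples$sample_class == "pdx", , drop = FALSE]
  type_of <- stats::setNames(cohort$samples$cancer_type,
                             cohort$samples$sample_id)
  sm_rows <- list()
  for (sid in pdx$sample_id) {
    a <- alts[alts$sample_id == sid, , drop = FALSE]
    m <- match_alterations_to_arms(a, type_of[[sid]], rules)
    if (nrow(m) > 0L) {
      sm_rows[[length(sm_rows) + 1L]] <- data.frame(sample_id = sid, m,
                                                    stringsAsFactors = FALSE)
    }
  }
  sample_matches <- do.call(rbind, sm_rows)
  if (is.null(sample_matches)) {
    sample_matches <- data.frame(sample_id = character(), arm_id = character(),
                                 drug = character(), n_alterations = integer(),
                                 alteration_keys = character(),
                                 stringsAsFactors = FALSE)
  }
  model_of <- stats::setNames(pdx$model_id, pdx$sample_id)
  model_matches <- unique(data.frame(
    model_id = model_of[sample_matches$sample_id],
    arm_id = sample_matches$arm_id, stringsAsFactors = FALSE))
  rownames(model_matches) <- NULL
  model_ids <- unique(pdx$model_id)
  classification <- classify_models(model_matches, model_ids)
  arm_scores <- list()
  for (arm in unique(model_matches$arm_id)) {
    pos <- sample_matches$sample_id[sample_matches$arm_id == arm]
    mm <- model_matches$model_id[model_matches$arm_id == arm]
    arm_scores[[arm]] <- s_arm_score(pos, mm, cohort$samples)
  }
  list(sample_matches = sample_matches, model_matches = model_matches,
       classification = classification, arm_scores = arm_scores,
       alterations = alts)
}
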