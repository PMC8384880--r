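# Assemble a FilterDecision table: input calls + key/retained/failed_rules.
# `fails` is a named list of logical fail vectors, evaluated in order.
decision_table <- function(calls, fails) {
  if (nrow(calls) == 0L) {
    calls$key <- character(0)
    calls$retained <- logical(0)
    calls$failed_rules <- character(0)
    return(calls)
  }
  fm <- do.call(cbind, fails)
  failed <- apply(fm, 1L, function(z) join_rules(names(fails)[z]))
  calls$key <- mutation_key(calls)
  calls$retained <- !apply(fm, 1L, any)
  calls$failed_rules <- failed
  calls
}

n_callers <- function(callers) {
  lengths(strsplit(ifelse(is.na(callers) | callers == "", "", callers), ","))
}

vaf_of <- function(alt, depth) ifelse(depth > 0, alt / depth, 0)

#' Tumor/normal consensus somatic filter
#'
#' High-confidence somatic calls require support from at least 2 callers, at
#' least 14 total reads in the tumor and 8 in the normal, at least 4 reads
#' carrying the variant allele, tumor VAF of at least 0.05, and normal VAF of
#' at most 0.01 (boundary values are retained: the discard rules are strict
#' "less than 0.05 in tumor" / "higher than 0.01 in normal"). Normal VAF is
#' `n_alt / n_depth` with 0/0 treated as 0.
#'
#' @param calls MAF-like data frame with `callers` (comma-separated string),
#'   `t_depth`, `t_alt`, `n_depth`, `n_alt` (plus the key columns
#'   `chrom`, `pos`, `ref`, `alt`).
#' @return the calls with `key`, `retained`, and `failed_rules` columns; a
#'   call is retained iff `failed_rules` is empty.
#' @export
consensus_filter <- function(calls) {
  if (nrow(calls) > 0 && all(is.na(calls$n_depth))) {
    stop("normal read counts absent: use tumor_only_filter() for tumor-only mode",
         call. = FALSE)
  }
  t_vaf <- vaf_of(calls$t_alt, calls$t_depth)
  n_vaf <- vaf_of(calls$n_alt, calls$n_depth)
  decision_table(calls, list(
    min_callers = n_callers(calls$callers) < 2L,
    min_t_depth = calls$t_depth < 14L,
    min_n_depth = calls$n_depth < 8L,
    min_t_alt   = calls$t_alt < 4L,
    min_t_vaf   = t_vaf < 0.05,
    max_n_vaf   = n_vaf > 0.01))
}

#' Tumor-only somatic filter
#'
#' Without a matched normal, calls require at least 20x site coverage, more
#' than 3 reads supporting the variant, and tumor VAF of at least 0.1.
#'
#' @inheritParams consensus_filter
#' @return FilterDecision table (see [consensus_filter()]).
#' @export
tumor_only_filter <- function(calls) {
  t_vaf <- vaf_of(calls$t_alt, calls$t_depth)
  decision_table(calls, list(
    min_t_depth = calls$t_depth < 20L,
    min_t_alt   = calls$t_alt <= 3L,
    min_t_vaf   = t_vaf < 0.1))
}

#' PDX-specific false-positive filter
#'
#' Even after mouse-read removal, PDX samples carry excess false positives
#' from residual mouse-homologous reads. A PDX call (already past the
#' depth/consensus cascade) is retained iff it appears in the known-somatic
#' whitelist, or the identical (chrom, pos, ref, alt) key is present in the
#' case's matched human tumor. When no matched human tumor exists, the
#' whitelist alone decides.
#'
#' @param pdx_calls calls from a PDX sample, with a logical `whitelist`
#'   column.
#' @param human_calls calls from the matched human tumor, or `NULL` when the
#'   case has none.
#' @return FilterDecision table.
#' @export
pdx_fp_filter <- function(pdx_calls, human_calls = NULL) {
  in_human <- if (is.null(human_calls) || nrow(human_calls) == 0L) {
    rep(FALSE, nrow(pdx_calls))
  } else {
    mutation_key(pdx_calls) %in% mutation_key(human_calls)
  }
  decision_table(pdx_calls, list(
    pdx_fp = !(pdx_calls$whitelist | in_human)))
}

#' Remove SNVs near retained indels
#'
#' Alignment artifacts cluster around indels, so point mutations within a
#' 20 bp window of a retained indel's anchor position (same sample, same
#' chromosome, |delta pos| <= window) are removed. Multi-base indels are
#' anchored at their leftmost position. Indels themselves always pass.
#'
#' @param calls table containing the retained SNVs and indels of one or more
#'   samples, with a `variant_type` column (`"snv"` / `"indel"`).
#' @param window half-width in bp (default 20).
#' @return FilterDecision table.
#' @export
indel_proximity_filter <- function(calls, window = 20) {
  near <- rep(FALSE, nrow(calls))
  if (nrow(calls) > 0L) {
    is_indel <- calls$variant_type == "indel"
    for (grp in split(seq_len(nrow(calls)),
                      paste(calls$sample_id, calls$chrom))) {
      ip <- calls$pos[grp][is_indel[grp]]
      if (length(ip) == 0L) next
      sv <- grp[!is_indel[grp]]
      if (length(sv) == 0L) next
      d <- outer(calls$pos[sv], ip, function(a, b) abs(a - b))
      near[sv] <- apply(d <= window, 1L, any)
    }
  }
  decision_table(calls, list(near_indel = near))
}

#' Germline pathogenic-variant post-filters
#'
#' Applies the retention rules downstream of pathogenicity labeling: at least
#' 5 reads supporting the alternative allele, VAF of at least 20%, cohort
#' minor-allele frequency of at most 1% (variants common in the cohort are
#' excluded), population allele frequency of at most 0.05%, and membership of
#' the cancer-predisposition gene list. For tumor-only cases, keys present in
#' the somatic call set or the known-somatic whitelist are additionally
#' dropped. Missing population AF is treated as 0 with a warning.
#'
#' @param calls data frame with key columns plus `sample_id`, `gene`,
#'   `ad_alt`, `depth`, `pop_af`.
#' @param predisposition_genes character vector of gene symbols.
#' @param n_samples cohort size used for the cohort-MAF denominator
#'   (default: number of distinct `sample_id`s in `calls`).
#' @param tumor_only logical; apply the somatic/whitelist exclusion.
#' @param somatic_keys,whitelist_keys character keys for the tumor-only
#'   exclusion (see [mutation_key()]).
#' @return FilterDecision table.
#' @export
germline_post_filter <- function(calls, predisposition_genes,
                                 n_samples = length(unique(calls$sample_id)),
                                 tumor_only = FALSE,
                                 somatic_keys = character(0),
                                 whitelist_keys = character(0)) {
  pop_af <- calls$pop_af
  if (anyNA(pop_af)) {
    warning(sprintf("%d call(s) with missing population AF treated as 0",
                    sum(is.na(pop_af))))
    pop_af[is.na(pop_af)] <- 0
  }
  key <- mutation_key(calls)
  carriers <- table(unique(data.frame(key, calls$sample_id))$key)
  cohort_maf <- as.numeric(carriers[key]) / n_samples
  vaf <- vaf_of(calls$ad_alt, calls$depth)
  fails <- list(
    min_ad     = calls$ad_alt < 5L,
    min_vaf    = vaf < 0.20,
    cohort_maf = cohort_maf > 0.01,
    pop_af     = pop_af > 0.0005,
    gene_list  = !(calls$gene %in% predisposition_genes))
  if (tumor_only) {
    fails$somatic_overlap <- key %in% c(somatic_keys, whitelist_keys)
  }
  decision_table(calls, fails)
}

#' Run the full somatic retention cascade on a cohort
#'
#' Convenience wrapper: applies the tumor/normal consensus filter (or the
#' tumor-only filter for cases lacking a human normal), then the PDX
#' false-positive filter against the matched human tumor and whitelist, then
#' the indel-proximity filter, per sample.
#'
#' @param cohort a `pdx_cohort`.
#' @return the retained calls (rows of `cohort$mutations` surviving every
#'   stage), with a `key` column.
#' @export
filter_cohort_mutations <- function(cohort) {
  out <- list()
  samples <- cohort$samples
  for (cid in unique(samples$case_id)) {
    cs <- samples[samples$case_id == cid, , drop = FALSE]
    has_normal <- any(cs$sample_class == "human_normal")
    ht_id <- cs$sample_id[cs$sample_class == "human_tumor"]
    stage1 <- function(m) {
      if (nrow(m) == 0L) return(m)
      d <- if (has_normal) consensus_filter(m) else tumor_only_filter(m)
      d[d$retained, setdiff(names(d), c("retained", "failed_rules")), drop = FALSE]
    }
    human_kept <- NULL
    if (length(ht_id) == 1L) {
      hm <- cohort$mutations[cohort$mutations$sample_id == ht_id, , drop = FALSE]
      hk <- stage1(hm)
      d <- indel_proximity_filter(hk)
      human_kept <- d[d$retained, names(hk), drop = FALSE]
      out[[length(out) + 1L]] <- human_kept
    }
    for (sid in cs$sample_id[cs$sample_class == "pdx"]) {
      m <- cohort$mutations[cohort$mutations$sample_id == sid, , drop = FALSE]
      kept <- stage1(m)
      if (nrow(kept) > 0L) {
        d <- pdx_fp_filter(kept, human_kept)
        kept <- d[d$retained, names(kept), drop = FALSE]
      }
      if (nrow(kept) > 0L) {
        d <- indel_proximity_filter(kept)
        kept <- d[d$retained, names(kept), drop = FALSE]
      }
      kept$key <- if (nrow(kept) > 0L) mutation_key(kept) else character(0)
      out[[length(out) + 1L]] <- kept
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
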