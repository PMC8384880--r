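#' Categorize copy number from log2 ratios
#'
#' Bins log2 ratios at the thresholds -1.3, -0.4, 0.3, 0.9 into deletion,
#' loss, neutral, gain, amplification. Upper bounds are inclusive: a value
#' exactly at a threshold falls in the lower bin (so log2 = 0.9 is a gain).
#'
#' @param log2_ratio numeric vector; non-finite values are an error.
#' @param thresholds the four cut points, ascending.
#' @return character vector of categories.
#' @export
call_cn_category <- function(log2_ratio,
                             thresholds = c(-1.3, -0.4, 0.3, 0.9)) {
  if (any(!is.finite(log2_ratio))) {
    stop("non-finite log2 ratio", call. = FALSE)
  }
  cats <- c("deletion", "loss", "neutral", "gain", "amplification")
  # findInterval with left.open gives upper-inclusive bins
  cats[findInterval(log2_ratio, thresholds, left.open = TRUE) + 1L]
}

#' Integer copy number implied by a log2 ratio
#'
#' `round(2 * 2^log2)`; exposed so a strict "amplification means CN > 5"
#' definition can be applied downstream of the category bins.
#'
#' @inheritParams call_cn_category
#' @export
log2_to_cn <- function(log2_ratio) as.integer(round(2 * 2^log2_ratio))

#' Drop low-quality copy-number segments
#'
#' Removes segments with mean coverage below 20, fewer than 10 probes, or
#' length under 5 kb (a segment of exactly 5,000 bp is retained: the drop
#' rule is strict "< 5 kb").
#'
#' @param segments SEG-like data frame with `coverage`, `n_probes`, `start`,
#'   `end` (0-based half-open).
#' @return the retained segments.
#' @export
segment_quality_filter <- function(segments) {
  keep <- segments$coverage >= 20 & segments$n_probes >= 10L &
    (segments$end - segments$start) >= 5000
  segments[keep, , drop = FALSE]
}

#' Genome fractions affected by deletions and amplifications
#'
#' Deleted fraction counts bp in the deletion and loss categories; amplified
#' counts gain and amplification (counting only the extreme categories is
#' switchable). A sample is deletion-abundant when its deleted fraction
#' strictly exceeds its amplified fraction.
#'
#' @param segments retained, non-overlapping segments of one sample.
#' @param covered_genome_bp denominator; defaults to total segment length.
#' @param extreme_only count only `deletion` / `amplification` bp.
#' @return list `(frac_deleted, frac_amplified, frac_neutral,
#'   deletion_abundant)`.
#' @export
genome_fractions <- function(segments, covered_genome_bp = NULL,
                             extreme_only = FALSE) {
  len <- segments$end - segments$start
  covered <- covered_genome_bp %||% sum(len)
  if (is.null(covered) || covered <= 0) {
    stop("covered genome length must be positive", call. = FALSE)
  }
  cat <- call_cn_category(segments$log2)
  del_set <- if (extreme_only) "deletion" else c("deletion", "loss")
  amp_set <- if (extreme_only) "amplification" else c("gain", "amplification")
  fd <- sum(len[cat %in% del_set]) / covered
  fa <- sum(len[cat %in% amp_set]) / covered
  fn <- sum(len[cat == "neutral"]) / covered
  list(frac_deleted = fd, frac_amplified = fa, frac_neutral = fn,
       deletion_abundant = fd > fa)
}

#' Whole-genome duplication call from allele-specific segments
#'
#' Proxy for a full allele-specific factorization: a sample is called WGD
#' when more than half of its (length-weighted) autosomal genome carries
#' major allele copy number of at least 2.
#'
#' @param segments retained segments of one sample with `major_cn`.
#' @param min_fraction length fraction threshold (default 0.5, strict).
#' @return `TRUE`/`FALSE`, or `NA` when allele-specific fields are absent
#'   (never silently `FALSE`).
#' @export
call_wgd <- function(segments, min_fraction = 0.5) {
  if (!"major_cn" %in% names(segments) || all(is.na(segments$major_cn))) {
    return(NA)
  }
  ok <- !is.na(segments$major_cn)
  len <- segments$end[ok] - segments$start[ok]
  sum(len[segments$major_cn[ok] >= 2L]) / sum(len) > min_fraction
}

#' TP53 LOH from SNP allelic balance
#'
#' Loss of heterozygosity shifts the B-allele fractions (BAFs) of
#' heterozygous germline SNPs away from 0.5. Within a 6 Mb window around
#' TP53, LOH is called when the mean allelic imbalance `mean(|BAF - 0.5|)`
#' exceeds the imbalance threshold.
#'
#' @param bafs data frame with `pos` and `baf` for one sample (already
#'   restricted to, or restrictable to, the window).
#' @param window optional `c(start, end)` filter on `pos`.
#' @param min_snps minimum informative SNPs for a call (default 10).
#' @param imbalance_threshold mean |BAF - 0.5| above which LOH is called
#'   (default 0.25).
#' @return `TRUE`/`FALSE`, or `NA` when fewer than `min_snps` SNPs are
#'   available (not-applicable).
#' @export
detect_tp53_loh <- function(bafs, window = NULL, min_snps = 10,
                            imbalance_threshold = 0.25) {
  b <- bafs$baf
  if (!is.null(window)) b <- b[bafs$pos >= window[1] & bafs$pos <= window[2]]
  b <- b[!is.na(b)]
  if (length(b) < min_snps) return(NA)
  mean(abs(b - 0.5)) > imbalance_threshold
}

#' Flag intra- and inter-sample CNA subclonality
#'
#' Intra-sample subclonality: a retained segment's fractional total copy
#' number deviates from the nearest integer by more than 0.1 (honoring the
#' 10% minimum clone proportion of the upstream inference). Inter-sample
#' subclonality (per case): a sample carries a categorized non-neutral
#' segment that no other sample of the same case matches at reciprocal
#' overlap >= 0.5 with the same category.
#'
#' @param segments retained segments of all samples (with `frac_cn`).
#' @param samples sample metadata (`sample_id`, `case_id`).
#' @param min_overlap reciprocal-overlap threshold (default 0.5).
#' @return data frame `(sample_id, intra_subclonal, inter_subclonal)`;
#'   `inter_subclonal` is `NA` for single-sample cases.
#' @export
flag_subclonality <- function(segments, samples, min_overlap = 0.5) {
  segments$category <- call_cn_category(segments$log2)
  ids <- intersect(samples$sample_id, unique(segments$sample_id))
  case_of <- stats::setNames(samples$case_id, samples$sample_id)
  intra <- vapply(ids, function(sid) {
    fc <- segments$frac_cn[segments$sample_id == sid]
    any(abs(fc - round(fc)) > 0.1, na.rm = TRUE)
  }, TRUE)
  inter <- rep(NA, length(ids))
  names(inter) <- ids
  for (cid in unique(case_of[ids])) {
    members <- ids[case_of[ids] == cid]
    if (length(members) < 2L) next
    for (sid in members) {
      own <- segments[segments$sample_id == sid &
                      segments$category != "neutral", , drop = FALSE]
      if (nrow(own) == 0L) { inter[sid] <- FALSE; next }
      others <- segments[segments$sample_id %in% setdiff(members, sid), ,
                         drop = FALSE]
      private <- vapply(seq_len(nrow(own)), function(i) {
        o <- own[i, ]
        cand <- others[others$chrom == o$chrom & others$category == o$category, ,
                       drop = FALSE]
        if (nrow(cand) == 0L) return(TRUE)
        ov <- pmin(cand$end, o$end) - pmax(cand$start, o$start)
        rec <- ov >= min_overlap * (o$end - o$start) &
               ov >= min_overlap * (cand$end - cand$start)
        !any(rec)
      }, TRUE)
      inter[sid] <- any(private)
    }
  }
  data.frame(sample_id = ids, intra_subclonal = unname(intra),
             inter_subclonal = unname(inter), stringsAsFactors = FALSE)
}

#' Per-sample copy-number feature summary
#'
#' Applies the quality filter and derives, per sample: genome fractions,
#' deletion abundance, WGD, and TP53 LOH (from the cohort BAF table), plus
#' subclonality flags.
#'
#' @param cohort a `pdx_cohort` (or a list with `segments`, `bafs`,
#'   `samples`, `config`).
#' @return data frame of `SampleCNFeatures`.
#' @export
sample_cn_features <- function(cohort) {
  segs <- segment_quality_filter(cohort$segments)
  w <- cohort$config$tp53_locus
  half <- (cohort$config$loh_window_bp %||% 6e6) / 2
  mid <- (w$start + w$end) / 2
  sub <- flag_subclonality(segs, cohort$samples)
  rows <- lapply(unique(segs$sample_id), function(sid) {
    s <- segs[segs$sample_id == sid, , drop = FALSE]
    fr <- genome_fractions(s)
    b <- cohort$bafs[cohort$bafs$sample_id == sid, , drop = FALSE]
    data.frame(sample_id = sid,
               frac_deleted = fr$frac_deleted,
               frac_amplified = fr$frac_amplified,
               deletion_abundant = fr$deletion_abundant,
               wgd = call_wgd(s),
               tp53_loh = detect_tp53_loh(b, window = c(mid - half, mid + half)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  merge(out, sub, by = "sample_id", all.x = TRUE, sort = TRUE)
}

#' Pearson chi-squared association between two binary features
#'
#' Builds the 2x2 contingency table and applies Pearson's chi-squared test
#' without continuity correction (1 df). A feature with a constant margin
#' makes the test undefined and is an error, as is n < 4.
#'
#' @param feature_a,feature_b logical vectors of equal length (pairs with an
#'   `NA` are dropped).
#' @return list `(chi2, p_value, table)`.
#' @export
association_test <- function(feature_a, feature_b) {
  stopifnot(length(feature_a) == length(feature_b))
  ok <- !is.na(feature_a) & !is.na(feature_b)
  a <- factor(feature_a[ok], levels = c(FALSE, TRUE))
  b <- factor(feature_b[ok], levels = c(FALSE, TRUE))
  if (sum(ok) < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  tab <- table(a, b)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    stop("degenerate margins: a feature is constant, test undefined",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p_value = unname(ct$p.value), table = tab)
}
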