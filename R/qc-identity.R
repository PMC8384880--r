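#' Germline SNP VAF concordance between two samples
#'
#' Identity QC for sequencing cohorts: two samples from the same individual
#' have near-identical germline variant allele fractions at a fixed panel of
#' common SNPs, while unrelated individuals do not. The statistic is the
#' Pearson correlation of raw VAFs over loci covered at `min_depth` or more
#' in both samples (genotype concordance, a discretized cross-check, is
#' available via [genotype_concordance()]).
#'
#' @param snp SNP panel as produced by [generate_cohort()]: a list with
#'   `loci`, `vaf` (loci x samples), and `depth` matrices.
#' @param a,b sample identifiers (columns of the matrices).
#' @param min_depth minimum locus depth in both samples (default 8).
#' @param min_loci minimum number of usable shared loci for a correlation
#'   (default 200); fewer is an insufficient-data error.
#' @return data frame row: `sample_id_a`, `sample_id_b`, `n_shared_loci`,
#'   `correlation`.
#' @export
vaf_concordance <- function(snp, a, b, min_depth = 8, min_loci = 200) {
  stopifnot(a %in% colnames(snp$vaf), b %in% colnames(snp$vaf), min_depth >= 1)
  ok <- snp$depth[, a] >= min_depth & snp$depth[, b] >= min_depth &
    !is.na(snp$vaf[, a]) & !is.na(snp$vaf[, b])
  n <- sum(ok)
  if (n < min_loci) {
    stop(sprintf("only %d shared loci at depth >= %d (need >= %d)",
                 n, min_depth, min_loci), call. = FALSE)
  }
  r <- stats::cor(snp$vaf[ok, a], snp$vaf[ok, b])
  data.frame(sample_id_a = a, sample_id_b = b, n_shared_loci = n,
             correlation = r, stringsAsFactors = FALSE)
}

#' @rdname vaf_concordance
#' @export
genotype_concordance <- function(snp, a, b, min_depth = 8, min_loci = 200) {
  ok <- snp$depth[, a] >= min_depth & snp$depth[, b] >= min_depth &
    !is.na(snp$vaf[, a]) & !is.na(snp$vaf[, b])
  if (sum(ok) < min_loci) {
    stop("insufficient shared loci for genotype concordance", call. = FALSE)
  }
  gt <- function(v) findInterval(v, c(0.2, 0.8))  # 0 / het / hom
  mean(gt(snp$vaf[ok, a]) == gt(snp$vaf[ok, b]))
}

#' Classify a concordance record into match / mismatch / ambiguous
#'
#' Thresholds are engineering defaults chosen so that self, contaminated,
#' relative-like, and unrelated profiles separate cleanly; the ambiguous band
#' between them is where contamination candidates (and close relatives) land.
#' At typical panel depths, self pairs correlate above 0.98 while a 30
#' percent contamination already drops below 0.93, hence the high match
#' threshold.
#'
#' @param record output row of [vaf_concordance()], or a bare correlation.
#' @param match_threshold correlation at or above which the pair is a match.
#' @param mismatch_threshold correlation at or below which it is a mismatch.
#' @return the record with a `verdict` column (or the verdict string for a
#'   bare correlation input).
#' @export
classify_pair <- function(record, match_threshold = 0.95, mismatch_threshold = 0.40) {
  stopifnot(mismatch_threshold < match_threshold)
  r <- if (is.data.frame(record)) record$correlation else record
  verdict <- ifelse(r >= match_threshold, "match",
                    ifelse(r <= mismatch_threshold, "mismatch", "ambiguous"))
  if (is.data.frame(record)) {
    record$verdict <- verdict
    record
  } else verdict
}

#' All-pairs concordance matrix
#'
#' @inheritParams vaf_concordance
#' @param sample_ids samples to include (default all columns).
#' @return long-format data frame of all unordered pairs with verdicts.
#' @export
concordance_table <- function(snp, sample_ids = colnames(snp$vaf),
                              min_depth = 8, min_loci = 200,
                              match_threshold = 0.95, mismatch_threshold = 0.40) {
  pairs <- utils::combn(sample_ids, 2)
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    rows[[k]] <- vaf_concordance(snp, pairs[1, k], pairs[2, k],
                                 min_depth = min_depth, min_loci = min_loci)
  }
  classify_pair(do.call(rbind, rows), match_threshold, mismatch_threshold)
}

#' Pedigree-consistency report from germline concordance
#'
#' Flags samples whose germline profile is inconsistent with their declared
#' case: a sample whose best-matching profile belongs to a different case
#' (swap candidate), and any sample classified as a mismatch against the
#' majority of its own case.
#' Within-case pairs in the ambiguous band are reported separately as
#' contamination candidates for manual review. Cases with a single sample
#' cannot be verified and are reported as such, not as failures.
#'
#' @param snp SNP panel (see [vaf_concordance()]).
#' @param samples sample metadata with `sample_id` and `case_id`.
#' @inheritParams concordance_table
#' @return list with elements `flagged` (character vector of sample ids),
#'   `ambiguous` (within-case ambiguous pairs), `unverifiable` (singleton-case
#'   samples), and `pairs` (the full concordance table).
#' @export
pedigree_check <- function(snp, samples, min_depth = 8, min_loci = 200,
                           match_threshold = 0.95, mismatch_threshold = 0.40) {
  ids <- intersect(samples$sample_id, colnames(snp$vaf))
  case_of <- stats::setNames(samples$case_id, samples$sample_id)
  tab_case <- table(case_of[ids])
  singletons <- ids[tab_case[case_of[ids]] == 1L]
  tab <- concordance_table(snp, ids, min_depth, min_loci,
                           match_threshold, mismatch_threshold)
  flagged <- character(0)
  for (sid in setdiff(ids, singletons)) {
    sel <- tab$sample_id_a == sid | tab$sample_id_b == sid
    sub <- tab[sel, , drop = FALSE]
    other <- ifelse(sub$sample_id_a == sid, sub$sample_id_b, sub$sample_id_a)
    best <- other[which.max(sub$correlation)]
    within_match <- any(sub$verdict == "match" & case_of[other] == case_of[sid])
    # a swapped-in profile perfectly matches the other case's samples, so a
    # cross-case best match alone must not flag samples that still match
    # their own case
    if (case_of[best] != case_of[sid] && !within_match) {
      flagged <- c(flagged, sid)
    }
    # an impostor mismatches most of its own case; its innocent partners
    # mismatch only the impostor, so require a majority to flag
    within <- sub[case_of[other] == case_of[sid], , drop = FALSE]
    if (nrow(within) > 0L && mean(within$verdict == "mismatch") > 0.5) {
      flagged <- c(flagged, sid)
    }
  }
  same_case <- case_of[tab$sample_id_a] == case_of[tab$sample_id_b]
  ambiguous <- tab[same_case & tab$verdict == "ambiguous", , drop = FALSE]
  list(flagged = sort(unique(flagged)),
       ambiguous = ambiguous,
       unverifiable = singletons,
       pairs = tab)
}

#' Coverage-based sample QC
#'
#' A WES sample passes with coding-region coverage above 20x; an RNA sample
#' with more than 25 Mb of mapped depth.
#'
#' @param qc data frame with `sample_id`, `assay` (`"wes"` or `"rna"`), and
#'   the corresponding metric column `coding_coverage_x` or `mapped_depth_mb`.
#' @return the input with a logical `pass` column.
#' @export
coverage_qc <- function(qc) {
  stopifnot(all(qc$assay %in% c("wes", "rna")))
  qc$pass <- ifelse(qc$assay == "wes",
                    qc$coding_coverage_x > 20,
                    qc$mapped_depth_mb > 25)
  qc
}
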