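#' Plant sample swaps and contaminations into a cohort
#'
#' Applies a plan of identity anomalies of the kind large sequencing cohorts
#' occasionally contain. A `swap` exchanges two samples' germline SNP profiles
#' and their variant tables; a `contaminate` replaces sample A's SNP VAFs by
#' the convex mixture `(1 - frac) * A + frac * B`. Every applied anomaly is
#' recorded in `truth$anomalies` so detection can be scored.
#'
#' @param cohort a `pdx_cohort`.
#' @param plan data frame with columns `type` (`"swap"` or `"contaminate"`),
#'   `sample_a`, `sample_b`, and `frac` (mixture fraction, used by
#'   contamination only; must lie strictly in (0, 1)).
#' @return the modified cohort. An empty or NULL plan returns the cohort
#'   unchanged.
#' @export
plant_anomalies <- function(cohort, plan) {
  stopifnot(inherits(cohort, "pdx_cohort"))
  if (is.null(plan) || nrow(plan) == 0L) return(cohort)
  stopifnot(all(c("type", "sample_a", "sample_b") %in% names(plan)))
  ids <- cohort$samples$sample_id
  for (i in seq_len(nrow(plan))) {
    a <- plan$sample_a[i]; b <- plan$sample_b[i]
    if (!a %in% ids || !b %in% ids) {
      stop(sprintf("unknown sample_id in anomaly plan: %s / %s", a, b),
           call. = FALSE)
    }
    if (plan$type[i] == "swap") {
      tmp <- cohort$snp$vaf[, a]
      cohort$snp$vaf[, a] <- cohort$snp$vaf[, b]
      cohort$snp$vaf[, b] <- tmp
      tmp <- cohort$snp$depth[, a]
      cohort$snp$depth[, a] <- cohort$snp$depth[, b]
      cohort$snp$depth[, b] <- tmp
      sel_a <- cohort$mutations$sample_id == a
      sel_b <- cohort$mutations$sample_id == b
      cohort$mutations$sample_id[sel_a] <- b
      cohort$mutations$sample_id[sel_b] <- a
      frac <- NA_real_
    } else if (plan$type[i] == "contaminate") {
      frac <- plan$frac[i]
      if (is.na(frac) || frac <= 0 || frac >= 1) {
        stop("contamination `frac` must lie strictly in (0, 1)", call. = FALSE)
      }
      va <- cohort$snp$vaf[, a]; vb <- cohort$snp$vaf[, b]
      mix <- (1 - frac) * va + frac * vb
      # loci missing in the contaminant stay at A's value
      mix[is.na(vb)] <- va[is.na(vb)]
      cohort$snp$vaf[, a] <- mix
    } else {
      stop(sprintf("unknown anomaly type '%s'", plan$type[i]), call. = FALSE)
    }
    cohort$truth$anomalies <- rbind(
      cohort$truth$anomalies,
      data.frame(type = plan$type[i], sample_a = a, sample_b = b, frac = frac,
                 stringsAsFactors = FALSE))
  }
  cohort
}
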