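#' Built-in gene annotation for the synthetic genome
#'
#' A small panel of cancer genes placed on a 22-autosome synthetic genome
#' (100 Mb per chromosome, coordinates loosely modeled on GRCh38 where a gene
#' has a well-known locus, e.g. TP53 on chr17 near 7.67 Mb). Downstream
#' modules use this table for gene-level copy-number categorization and for
#' treatment-arm matching; it is data, not a hard-coded assumption, and can be
#' replaced by any table with the same columns.
#'
#' @return data frame with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
pdx_gene_table <- function() {
  g <- list(
    # gene, chrom, start (bp)
    c("TP53",   "chr17",  7668000),
    c("ERBB2",  "chr17", 39688000),
    c("NF1",    "chr17", 31094000),
    c("BRCA1",  "chr17", 43044000),
    c("PIK3CA", "chr3", 179148000),
    c("CTNNB1", "chr3",  41194000),
    c("FGFR3",  "chr4",   1793000),
    c("TACC3",  "chr4",   1721000),
    c("KIT",    "chr4",  54657000),
    c("KRAS",   "chr12", 25205000),
    c("CCND2",  "chr12",  4273000),
    c("BRAF",   "chr7", 40753000),
    c("EGFR",   "chr7",  55019000),
    c("MET",    "chr7",  16002000),
    c("CDK6",   "chr7",  92604000),
    c("PTEN",   "chr10", 87863000),
    c("FGFR2",  "chr10", 21498000),
    c("CCND1",  "chr11", 69641000),
    c("ATM",    "chr11", 8253000),
    c("BRCA2",  "chr13", 32315000),
    c("RB1",    "chr13", 48303000),
    c("AKT1",   "chr14", 4769000),
    c("APC",    "chr5", 12043000),
    c("FGFR1",  "chr8", 38411000),
    c("MYC",    "chr8", 27736000),
    c("CDKN2A", "chr9", 21967000),
    c("NOTCH1", "chr9", 36494000),
    c("SMAD4",  "chr18", 51030000),
    c("STK11",  "chr19", 1205000),
    c("GNAS",   "chr20", 58839000)
  )
  df <- data.frame(
    gene  = vapply(g, `[`, "", 1L),
    chrom = vapply(g, `[`, "", 2L),
    start = as.numeric(vapply(g, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  df$end <- df$start + 100e3
  df[order(df$gene), , drop = FALSE]
}

#' Configure a synthetic PDX cohort
#'
#' Bundles every parameter of the synthetic-cohort generator with defaults
#' describing the study conditions the analyses assume: human tumors of
#' moderate purity and PDXs of high purity, clonal mutations plus a handful of
#' subclones that pass through a model-specific engraftment bottleneck,
#' purity-dependent binomial read counts, a cohort-wide germline SNP panel,
#' whole-genome duplication (WGD) in about half the cases with TP53 LOH and
#' deletion abundance strongly associated with WGD, and a small number of
#' transcriptional groups separated by signature-gene shifts.
#'
#' @param seed mandatory RNG seed; fixing it fixes every emitted byte.
#' @param n_cases number of patient cases.
#' @param models_per_case,passages_per_model scalar or inclusive `(min, max)`
#'   range sampled per case/model. Passage indices run `0 .. n-1`.
#' @param human_tumor_prob,human_normal_prob probability a case has a human
#'   tumor / human normal sample. Cases without a normal are analyzed in
#'   tumor-only mode downstream.
#' @param cancer_types codes sampled uniformly per case.
#' @param purity_human,purity_pdx `c(shape1, shape2)` of the Beta purity laws
#'   (defaults center 0.50 and 0.85).
#' @param n_clonal_mutations truncal mutations per case.
#' @param n_subclones,subclone_mutations,subclone_ccf subclone count, private
#'   mutations per subclone, and the uniform range of subclone cancer-cell
#'   fractions in the human tumor.
#' @param bottleneck_prob probability each subclone survives engraftment of a
#'   model (independently per model; the trunk always survives).
#' @param passage_private_mutations new fixed mutations acquired by each PDX
#'   passage.
#' @param t_depth_mean,n_depth_mean Poisson means of tumor / normal depth.
#' @param indel_fraction,silent_fraction fraction of mutations that are
#'   indels / silent.
#' @param snv_caller_sens,indel_caller_sens named per-caller detection
#'   sensitivities for true variants.
#' @param fp_per_sample caller-specific false positives per tumor sample
#'   (single caller, weak read support).
#' @param whitelist_fraction fraction of true somatic mutations present in the
#'   known-somatic whitelist (drivers always are).
#' @param error_rate sequencing error rate driving alt reads in normals.
#' @param n_snp_loci,snp_af_range,snp_depth_mean germline SNP panel size,
#'   population allele-frequency range, and Poisson depth mean.
#' @param p_wgd probability a case is whole-genome duplicated.
#' @param p_tp53_loh,p_del_abundant named `c(wgd=, no_wgd=)` conditional
#'   probabilities of TP53 LOH / deletion abundance given WGD status.
#' @param n_baf_snps,baf_depth heterozygous SNPs simulated in the TP53 window
#'   and their Poisson depth mean.
#' @param tp53_locus `c(chrom, start, end)`-style list: chromosome plus
#'   0-based interval of the TP53 gene on the synthetic genome.
#' @param loh_window_bp width of the genomic window around TP53 used both to
#'   plant and to detect allelic imbalance (default 6 Mb).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param segments_per_chrom copy-number segments per chromosome.
#' @param p_intra_subclonal,p_private_segment probability a tumor sample
#'   carries a fractional-CN (intra-sample subclonal) segment / a private
#'   non-neutral segment absent from the rest of its case.
#' @param n_genes,n_expression_groups,signature_size,group_effect,noise_sd,
#'   baseline_mean,baseline_sd expression model: total genes, number of
#'   transcriptional groups, signature genes per group, signature shift in
#'   units of `noise_sd`, residual SD, and the baseline abundance law.
#' @param p_cluster_shift probability a PDX sample's expression group differs
#'   from its model's group (0 = perfectly stable models).
#' @param n_centers,center_offset_sd collection centers and the SD of
#'   per-gene, per-center batch offsets.
#' @param arm_spikes optional data frame `(arm_id, gene, class, n_models)`
#'   of treatment-arm alterations to plant; `class` is one of
#'   `non_silent_mutation`, `variant_whitelist`, `amplification`, `deletion`,
#'   `fusion`.
#' @param n_decoy_fusions low-FFPM / normal-panel fusion decoys per cohort.
#' @return object of class `pdx_cohort_config`.
#' @export
cohort_config <- function(seed,
                          n_cases = 6L,
                          models_per_case = 2L,
                          passages_per_model = 3L,
                          human_tumor_prob = 1,
                          human_normal_prob = 1,
                          cancer_types = c("BRCA", "COAD", "LUAD", "PAAD", "SKCM", "SARC"),
                          purity_human = c(8, 8),
                          purity_pdx = c(17, 3),
                          n_clonal_mutations = 60L,
                          n_subclones = 3L,
                          subclone_mutations = 25L,
                          subclone_ccf = c(0.15, 0.6),
                          bottleneck_prob = 0.5,
                          passage_private_mutations = 5L,
                          t_depth_mean = 80,
                          n_depth_mean = 40,
                          indel_fraction = 0.12,
                          silent_fraction = 0.25,
                          snv_caller_sens = c(strelka = 0.98, mutect = 0.95, varscan = 0.90),
                          indel_caller_sens = c(strelka = 0.90, varscan = 0.85, pindel = 0.95),
                          fp_per_sample = 8L,
                          whitelist_fraction = 0.3,
                          error_rate = 0.001,
                          n_snp_loci = 1500L,
                          snp_af_range = c(0.1, 0.5),
                          snp_depth_mean = 60,
                          p_wgd = 0.5,
                          p_tp53_loh = c(wgd = 0.9, no_wgd = 0.2),
                          p_del_abundant = c(wgd = 0.9, no_wgd = 0.2),
                          n_baf_snps = 30L,
                          baf_depth = 100,
                          tp53_locus = list(chrom = "chr17", start = 7668000, end = 7768000),
                          loh_window_bp = 6e6,
                          chrom_lengths = stats::setNames(rep(100e6, 22), paste0("chr", 1:22)),
                          segments_per_chrom = 4L,
                          p_intra_subclonal = 0.2,
                          p_private_segment = 0.2,
                          n_genes = 600L,
                          n_expression_groups = 4L,
                          signature_size = 40L,
                          group_effect = 2,
                          noise_sd = 1,
                          baseline_mean = 6,
                          baseline_sd = 1.5,
                          p_cluster_shift = 0,
                          n_centers = 1L,
                          center_offset_sd = 0,
                          arm_spikes = NULL,
                          n_decoy_fusions = 3L) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  cfg <- as.list(environment())
  validate_cohort_config(cfg)
  class(cfg) <- "pdx_cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  chk_prob <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop(sprintf("`%s` must lie in [0, 1]", nm), call. = FALSE)
    }
  }
  chk_pos <- function(x, nm) {
    if (any(!is.finite(x)) || any(x <= 0)) {
      stop(sprintf("`%s` must be positive", nm), call. = FALSE)
    }
  }
  chk_pos(cfg$n_cases, "n_cases")
  chk_pos(cfg$models_per_case, "models_per_case")
  chk_pos(cfg$passages_per_model, "passages_per_model")
  chk_pos(cfg$n_snp_loci, "n_snp_loci")
  chk_pos(cfg$t_depth_mean, "t_depth_mean")
  chk_pos(cfg$n_genes, "n_genes")
  for (nm in c("human_tumor_prob", "human_normal_prob", "bottleneck_prob",
               "indel_fraction", "silent_fraction", "whitelist_fraction",
               "error_rate", "p_wgd", "p_intra_subclonal", "p_private_segment",
               "p_cluster_shift")) {
    chk_prob(cfg[[nm]], nm)
  }
  chk_prob(cfg$p_tp53_loh, "p_tp53_loh")
  chk_prob(cfg$p_del_abundant, "p_del_abundant")
  chk_prob(cfg$snv_caller_sens, "snv_caller_sens")
  chk_prob(cfg$indel_caller_sens, "indel_caller_sens")
  if (!all(c("wgd", "no_wgd") %in% names(cfg$p_tp53_loh))) {
    stop("`p_tp53_loh` needs elements named 'wgd' and 'no_wgd'", call. = FALSE)
  }
  if (!all(c("wgd", "no_wgd") %in% names(cfg$p_del_abundant))) {
    stop("`p_del_abundant` needs elements named 'wgd' and 'no_wgd'", call. = FALSE)
  }
  if (!is.null(cfg$arm_spikes)) {
    need <- c("arm_id", "gene", "class", "n_models")
    if (!all(need %in% names(cfg$arm_spikes))) {
      stop("`arm_spikes` needs columns arm_id, gene, class, n_models", call. = FALSE)
    }
    ok <- cfg$arm_spikes$class %in%
      c("non_silent_mutation", "variant_whitelist", "amplification", "deletion", "fusion")
    if (!all(ok)) stop("unknown arm_spikes class", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.pdx_cohort_config <- function(x, ...) {
  cat("<pdx_cohort_config>\n")
  cat(sprintf("  seed %d; %d cases; models/case %s; passages/model %s\n",
              as.integer(x$seed), as.integer(x$n_cases),
              paste(x$models_per_case, collapse = "-"),
              paste(x$passages_per_model, collapse = "-")))
  cat(sprintf("  P(WGD) = %.2f; P(TP53 LOH | WGD, no WGD) = %.2f / %.2f\n",
              x$p_wgd, x$p_tp53_loh[["wgd"]], x$p_tp53_loh[["no_wgd"]]))
  invisible(x)
}
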