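#' Write a synthetic cohort to standard file formats
#'
#' Emits the cohort as the plain-text formats downstream modules (and external
#' tools) consume: one VCF 4.2 per tumor sample plus a combined MAF-like TSV
#' for mutation calls, a SEG-like TSV for copy-number segments, TSV matrices
#' for expression and the germline SNP panel, a TSV of TP53-window B-allele
#' frequencies, a fusion TSV, a lineage JSON, and a truth JSON. Variant
#' positions are 1-based (VCF convention); segment intervals are 0-based
#' half-open (BED convention).
#'
#' @param cohort a `pdx_cohort`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @seealso [read_cohort()] for the lossless inverse.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "pdx_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    path
  }
  files <- c(
    wt(cohort$samples, "samples.tsv"),
    wt(cohort$mutations, "mutations.tsv"),
    wt(cohort$segments, "segments.tsv"),
    wt(cohort$bafs, "bafs.tsv"),
    wt(cohort$fusions, "fusions.tsv"),
    wt(cohort$snp$loci, "snp_loci.tsv"),
    wt(as.data.frame(cohort$snp$vaf, check.names = FALSE), "snp_vaf.tsv"),
    wt(as.data.frame(cohort$snp$depth, check.names = FALSE), "snp_depth.tsv"),
    wt(data.frame(gene = rownames(cohort$expression),
                  as.data.frame(cohort$expression, check.names = FALSE),
                  check.names = FALSE), "expression.tsv"))

  cfg <- cohort$config
  jsonlite::write_json(list(seed = cfg$seed, tp53_locus = cfg$tp53_locus,
                            loh_window_bp = cfg$loh_window_bp,
                            chrom_lengths = as.list(cfg$chrom_lengths)),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  lineage <- lapply(split(cohort$samples, cohort$samples$case_id), function(cs) {
    list(case_id = cs$case_id[1], cancer_type = cs$cancer_type[1],
         samples = cs[, c("sample_id", "sample_class", "model_id",
                          "passage_index", "parent_sample_id")])
  })
  jsonlite::write_json(unname(lineage), file.path(out_dir, "lineage.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                       dataframe = "rows", digits = NA, na = "null",
                       pretty = TRUE)

  vcf_dir <- file.path(out_dir, "vcf")
  dir.create(vcf_dir, showWarnings = FALSE)
  for (sid in unique(cohort$mutations$sample_id)) {
    files <- c(files, write_sample_vcf(cohort, sid, vcf_dir))
  }
  files <- c(files, file.path(out_dir, "lineage.json"),
             file.path(out_dir, "truth.json"))
  invisible(files)
}

write_sample_vcf <- function(cohort, sample_id, vcf_dir) {
  m <- cohort$mutations[cohort$mutations$sample_id == sample_id, , drop = FALSE]
  cl <- cohort$config$chrom_lengths
  m <- m[order(match(m$chrom, names(cl)), m$pos), , drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           "##source=pdxkit",
           sprintf("##contig=<ID=%s,length=%d>", names(cl), as.integer(cl)),
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect\">",
           "##INFO=<ID=CALLERS,Number=1,Type=String,Description=\"Supporting callers (bar-separated)\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_id), collapse = "\t"))
  info <- sprintf("GENE=%s;EFFECT=%s;CALLERS=%s", m$gene, m$effect,
                  gsub(",", "|", m$callers))
  body <- paste(m$chrom, m$pos, ".", m$ref, m$alt, ".", "PASS", info,
                "GT:AD:DP",
                sprintf("0/1:%d,%d:%d", m$t_depth - m$t_alt, m$t_alt, m$t_depth),
                sep = "\t")
  path <- file.path(vcf_dir, paste0(sample_id, ".vcf"))
  writeLines(c(hdr, body), path)
  path
}

#' Read a cohort written by [write_cohort()]
#'
#' Restores the data payload of a cohort from its on-disk representation. The
#' TSV and JSON files round-trip losslessly (up to floating-point printing
#' precision); the per-sample VCFs are a redundant export and are not needed
#' for reconstruction.
#'
#' @param dir directory produced by [write_cohort()].
#' @return a `pdx_cohort`; `config` is restored from `config.json` as the
#'   key geometry (seed, TP53 locus, LOH window, chromosome lengths), not
#'   the full generator configuration.
#' @export
read_cohort <- function(dir) {
  rd <- function(name, colClasses = NA) {
    utils::read.delim(file.path(dir, name), sep = "\t", header = TRUE,
                      colClasses = colClasses, check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
  samples <- rd("samples.tsv", c(sample_id = "character", case_id = "character",
                                 model_id = "character", sample_class = "character",
                                 passage_index = "integer",
                                 parent_sample_id = "character",
                                 cancer_type = "character", purity = "numeric",
                                 center = "character"))
  mutations <- rd("mutations.tsv", c(sample_id = "character", chrom = "character",
                                     pos = "integer", ref = "character",
                                     alt = "character", variant_type = "character",
                                     gene = "character", effect = "character",
                                     hotspot = "character", driver = "logical",
                                     callers = "character", t_depth = "integer",
                                     t_alt = "integer", n_depth = "integer",
                                     n_alt = "integer", whitelist = "logical"))
  segments <- rd("segments.tsv", c(sample_id = "character", chrom = "character",
                                   start = "numeric", end = "numeric",
                                   log2 = "numeric", n_probes = "integer",
                                   coverage = "numeric", major_cn = "integer",
                                   minor_cn = "integer", frac_cn = "numeric",
                                   category = "character"))
  bafs <- rd("bafs.tsv", c(sample_id = "character", chrom = "character",
                           pos = "integer", baf = "numeric", depth = "integer"))
  fusions <- rd("fusions.tsv", c(sample_id = "character", gene5 = "character",
                                 gene3 = "character", in_frame = "logical",
                                 ffpm = "numeric", annotation_tags = "character"))
  fusions$annotation_tags[is.na(fusions$annotation_tags)] <- ""
  loci <- rd("snp_loci.tsv", c(chrom = "character", pos = "integer",
                               pop_af = "numeric"))
  vaf <- as.matrix(rd("snp_vaf.tsv"))
  depth <- as.matrix(rd("snp_depth.tsv"))
  storage.mode(depth) <- "integer"
  rownames(vaf) <- rownames(depth) <- NULL
  expr_df <- rd("expression.tsv")
  expr <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expr) <- expr_df$gene

  truth_raw <- jsonlite::fromJSON(file.path(dir, "truth.json"),
                                  simplifyDataFrame = TRUE)
  truth <- lapply(truth_raw, function(x) {
    if (is.data.frame(x)) x else as.data.frame(x, stringsAsFactors = FALSE)
  })

  config <- NULL
  cfg_path <- file.path(dir, "config.json")
  if (file.exists(cfg_path)) {
    config <- jsonlite::fromJSON(cfg_path, simplifyDataFrame = FALSE)
    config$chrom_lengths <- unlist(config$chrom_lengths)
  }

  structure(list(samples = samples, mutations = mutations,
                 snp = list(loci = loci, vaf = vaf, depth = depth),
                 segments = segments, bafs = bafs, expression = expr,
                 fusions = fusions, truth = truth, config = config),
            class = "pdx_cohort")
}
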