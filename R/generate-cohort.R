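#' Generate a synthetic PDX cohort with known ground truth
#'
#' Simulates a cohort of patient cases, each with optional human tumor/normal
#' samples and one or more PDX models propagated through serial passages.
#' Somatic mutations are organized into a truncal clone plus subclones with
#' cancer-cell fractions (CCFs); each model passes through an engraftment
#' bottleneck in which every subclone independently survives with the
#' configured probability and surviving fractions renormalize. Read counts at
#' every variant are binomial draws with success probability
#' `purity x CCF x allele dosage / total copy number` (heterozygous diploid
#' default: `purity x CCF / 2`). Caller provenance, caller-specific false
#' positives, a cohort-wide germline SNP panel, copy-number segments with
#' allele-specific integer copy numbers, WGD / TP53-LOH states, B-allele
#' frequencies around TP53, expression group structure, fusions, and
#' treatment-arm alteration spike-ins are all generated and recorded in truth
#' tables.
#'
#' @param config a [cohort_config()] object; the seed it carries makes the
#'   output fully deterministic.
#' @return an object of class `pdx_cohort`: a list with elements `samples`,
#'   `mutations`, `snp` (`loci`, `vaf`, `depth`), `segments`, `bafs`,
#'   `expression`, `fusions`, `truth`, and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "pdx_cohort_config")) {
    stop("`config` must be created by cohort_config()", call. = FALSE)
  }
  with_seed(config$seed, build_cohort(config))
}

# background (non-druggable) gene symbol pool for bystander mutations
bg_gene_pool <- function() sprintf("BG%03d", 1:300)

draw_purity <- function(par, n) {
  if (length(par) == 1L) rep(as.numeric(par), n) else stats::rbeta(n, par[1], par[2])
}

random_hotspot_label <- function(n) {
  paste0(sample(LETTERS, n, TRUE), sample(100:999, n, TRUE), sample(LETTERS, n, TRUE))
}

# ---- case-level truth mutations ------------------------------------------

make_case_mutations <- function(cfg, case_id, chroms) {
  n_sub <- cfg$n_subclones
  counts <- c(cfg$n_clonal_mutations, rep(cfg$subclone_mutations, n_sub))
  n <- sum(counts)
  if (n == 0L) {
    return(data.frame(case_id = character(), clone = integer(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      variant_type = character(), gene = character(),
                      effect = character(), hotspot = character(),
                      driver = logical(), whitelist = logical(),
                      stringsAsFactors = FALSE))
  }
  clone <- rep(seq_along(counts) - 1L, counts)
  chrom <- sample(chroms, n, TRUE, prob = cfg$chrom_lengths / sum(cfg$chrom_lengths))
  pos <- floor(stats::runif(n, 1, cfg$chrom_lengths[chrom])) + 0
  is_indel <- stats::runif(n) < cfg$indel_fraction
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  ins <- stats::runif(n) < 0.5
  tail_len <- sample(1:3, n, TRUE)
  tails <- vapply(tail_len, function(k) paste(sample(bases, k, TRUE), collapse = ""), "")
  ref[is_indel & !ins] <- paste0(ref[is_indel & !ins], tails[is_indel & !ins])
  alt[is_indel & !ins] <- substr(ref[is_indel & !ins], 1L, 1L)
  alt[is_indel & ins] <- paste0(ref[is_indel & ins], tails[is_indel & ins])
  effect <- ifelse(stats::runif(n) < cfg$silent_fraction, "silent", "non_silent")
  gene <- sample(bg_gene_pool(), n, TRUE)
  driver <- rep(FALSE, n)
  cand <- which(clone == 0L & effect == "non_silent" & !is_indel)
  if (length(cand) > 0L) driver[sample(cand, min(2L, length(cand)))] <- TRUE
  hotspot <- rep(NA_character_, n)
  hotspot[driver] <- random_hotspot_label(sum(driver))
  whitelist <- driver | stats::runif(n) < cfg$whitelist_fraction
  data.frame(case_id = case_id, clone = clone, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt,
             variant_type = ifelse(is_indel, "indel", "snv"),
             gene = gene, effect = effect, hotspot = hotspot,
             driver = driver, whitelist = whitelist, stringsAsFactors = FALSE)
}

# observed calls for one tumor sample: binomial read counts + caller flags
observe_calls <- function(cfg, sample_id, muts, ccf, purity, has_normal) {
  n <- nrow(muts)
  if (n == 0L) return(NULL)
  vaf_exp <- pmin(1, purity * ccf / 2)
  t_depth <- stats::rpois(n, cfg$t_depth_mean)
  t_alt <- stats::rbinom(n, t_depth, vaf_exp)
  keep <- t_alt >= 2L & ccf > 0
  if (!any(keep)) return(NULL)
  muts <- muts[keep, , drop = FALSE]
  t_depth <- t_depth[keep]; t_alt <- t_alt[keep]
  m <- nrow(muts)
  callers <- character(m)
  for (i in seq_len(m)) {
    sens <- if (muts$variant_type[i] == "indel") cfg$indel_caller_sens else cfg$snv_caller_sens
    hit <- names(sens)[stats::runif(length(sens)) < sens]
    callers[i] <- paste(sort(hit), collapse = ",")
  }
  det <- callers != ""
  if (!any(det)) return(NULL)
  muts <- muts[det, , drop = FALSE]
  t_depth <- t_depth[det]; t_alt <- t_alt[det]; callers <- callers[det]
  m <- nrow(muts)
  if (has_normal) {
    n_depth <- stats::rpois(m, cfg$n_depth_mean)
    n_alt <- stats::rbinom(m, n_depth, cfg$error_rate)
  } else {
    n_depth <- rep(NA_integer_, m)
    n_alt <- rep(NA_integer_, m)
  }
  data.frame(sample_id = sample_id, chrom = muts$chrom, pos = muts$pos,
             ref = muts$ref, alt = muts$alt, variant_type = muts$variant_type,
             gene = muts$gene, effect = muts$effect, hotspot = muts$hotspot,
             driver = muts$driver, callers = callers,
             t_depth = t_depth, t_alt = t_alt,
             n_depth = n_depth, n_alt = n_alt,
             whitelist = muts$whitelist, stringsAsFactors = FALSE)
}

false_positive_calls <- function(cfg, sample_id, chroms, has_normal) {
  n <- cfg$fp_per_sample
  if (n == 0L) return(NULL)
  chrom <- sample(chroms, n, TRUE)
  pos <- as.integer(floor(stats::runif(n, 1, cfg$chrom_lengths[chrom])))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  is_indel <- stats::runif(n) < 0.15
  alt[is_indel] <- paste0(ref[is_indel], sample(bases, sum(is_indel), TRUE))
  all_callers <- union(names(cfg$snv_caller_sens), names(cfg$indel_caller_sens))
  t_depth <- stats::rpois(n, cfg$t_depth_mean)
  t_alt <- pmin(t_depth, sample(2:3, n, TRUE))
  if (has_normal) {
    n_depth <- stats::rpois(n, cfg$n_depth_mean)
    n_alt <- stats::rbinom(n, n_depth, cfg$error_rate)
  } else {
    n_depth <- rep(NA_integer_, n); n_alt <- rep(NA_integer_, n)
  }
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
             variant_type = ifelse(is_indel, "indel", "snv"),
             gene = sample(bg_gene_pool(), n, TRUE), effect = "non_silent",
             hotspot = NA_character_, driver = FALSE,
             callers = sample(all_callers, n, TRUE),
             t_depth = t_depth, t_alt = t_alt, n_depth = n_depth, n_alt = n_alt,
             whitelist = FALSE, stringsAsFactors = FALSE)
}

# ---- copy-number machinery ------------------------------------------------

cn_bands <- list(deletion = c(-2.2, -1.4), loss = c(-1.1, -0.5),
                 neutral = c(-0.3, 0.25), gain = c(0.35, 0.85),
                 amplification = c(0.95, 2.2))

cn_allele_map <- function(wgd) {
  if (wgd) {
    list(deletion = c(1L, 0L), loss = c(2L, 1L), neutral = c(2L, 2L),
         gain = c(3L, 2L), amplification = c(6L, 2L))
  } else {
    list(deletion = c(0L, 0L), loss = c(1L, 0L), neutral = c(1L, 1L),
         gain = c(2L, 1L), amplification = c(5L, 1L))
  }
}

draw_log2 <- function(category, n = length(category)) {
  lo <- vapply(category, function(k) cn_bands[[k]][1], 0)
  hi <- vapply(category, function(k) cn_bands[[k]][2], 0)
  stats::runif(n, lo, hi)
}

# Replace the part of one sample's segments overlapping [start, end) on
# `chrom` with a single segment carrying `override` fields; slivers shorter
# than 5 kb are dropped rather than emitted.
carve_segment <- function(segs, chrom, start, end, override) {
  hit <- segs$chrom == chrom & segs$start < end & segs$end > start
  if (!any(hit)) return(segs)
  keep <- segs[!hit, , drop = FALSE]
  pieces <- list()
  for (i in which(hit)) {
    s <- segs[i, , drop = FALSE]
    if (s$start < start && (start - s$start) >= 5000) {
      left <- s; left$end <- start; pieces[[length(pieces) + 1L]] <- left
    }
    if (s$end > end && (s$end - end) >= 5000) {
      right <- s; right$start <- end; pieces[[length(pieces) + 1L]] <- right
    }
  }
  mid <- segs[which(hit)[1], , drop = FALSE]
  mid$start <- max(start, min(segs$start[hit]))
  mid$end <- min(end, max(segs$end[hit]))
  for (nm in names(override)) mid[[nm]] <- override[[nm]]
  out <- rbind(keep, do.call(rbind, c(pieces, list(mid))))
  out$n_probes <- pmax(10L, as.integer(round((out$end - out$start) / 5e5)))
  out[order(out$chrom, out$start), , drop = FALSE]
}

case_segment_layout <- function(cfg, del_abundant, protected) {
  probs <- if (del_abundant) c(0.06, 0.22, 0.60, 0.09, 0.03)
           else c(0.02, 0.08, 0.60, 0.22, 0.08)
  cats <- names(cn_bands)
  rows <- vector("list", length(cfg$chrom_lengths))
  for (ci in seq_along(cfg$chrom_lengths)) {
    chrom <- names(cfg$chrom_lengths)[ci]
    L <- cfg$chrom_lengths[[ci]]
    k <- cfg$segments_per_chrom
    if (k > 1L) {
      frac <- seq_len(k - 1L) / k + stats::runif(k - 1L, -0.4 / k, 0.4 / k)
      brk <- sort(round(L * frac))
    } else brk <- numeric(0)
    start <- c(0, brk); end <- c(brk, L)
    category <- sample(cats, k, TRUE, prob = probs)
    rows[[ci]] <- data.frame(chrom = chrom, start = start, end = end,
                             category = category, stringsAsFactors = FALSE)
  }
  lay <- do.call(rbind, rows)
  if (nrow(protected) > 0L) {
    for (i in seq_len(nrow(protected))) {
      hit <- lay$chrom == protected$chrom[i] &
        lay$start < protected$end[i] + 2e6 & lay$end > protected$start[i] - 2e6
      lay$category[hit] <- "neutral"
    }
  }
  lay
}

sample_segments <- function(cfg, sample_id, layout, wgd, loh, purity,
                            intra_subclonal, private_seg, cn_overrides) {
  segs <- layout
  if (private_seg && nrow(segs) > 0L) {
    i <- sample(nrow(segs), 1L)
    segs$category[i] <- if (segs$category[i] == "neutral") {
      sample(c("gain", "loss"), 1L)
    } else "neutral"
  }
  amap <- cn_allele_map(wgd)
  mm <- t(vapply(segs$category, function(k) amap[[k]], integer(2)))
  segs$sample_id <- sample_id
  segs$log2 <- draw_log2(segs$category)
  segs$n_probes <- pmax(10L, as.integer(round((segs$end - segs$start) / 5e5)))
  segs$coverage <- pmax(21, round(stats::rnorm(nrow(segs), 60, 8), 1))
  segs$major_cn <- mm[, 1]
  segs$minor_cn <- mm[, 2]
  segs$frac_cn <- as.numeric(segs$major_cn + segs$minor_cn)
  if (loh) {
    w <- cfg$tp53_locus
    half <- cfg$loh_window_bp / 2
    mid <- (w$start + w$end) / 2
    major <- if (wgd) 4L else 2L
    segs <- carve_segment(segs, w$chrom, max(0, mid - half), mid + half,
                          list(category = "neutral",
                               log2 = stats::runif(1, -0.1, 0.1),
                               coverage = round(stats::rnorm(1, 60, 8), 1),
                               major_cn = major, minor_cn = 0L,
                               frac_cn = as.numeric(major)))
  }
  if (!is.null(cn_overrides) && nrow(cn_overrides) > 0L) {
    for (i in seq_len(nrow(cn_overrides))) {
      o <- cn_overrides[i, ]
      if (o$class == "amplification") {
        ov <- list(category = "amplification", log2 = stats::runif(1, 1.5, 2.2),
                   coverage = round(stats::rnorm(1, 60, 8), 1),
                   major_cn = 5L + 1L * wgd, minor_cn = 1L + 1L * wgd,
                   frac_cn = 6 + 2 * wgd)
      } else {
        ov <- list(category = "deletion", log2 = stats::runif(1, -2.2, -1.6),
                   coverage = round(stats::rnorm(1, 60, 8), 1),
                   major_cn = if (wgd) 1L else 0L, minor_cn = 0L,
                   frac_cn = if (wgd) 1 else 0)
      }
      segs <- carve_segment(segs, o$chrom, max(0, o$start - 1e6), o$end + 1e6, ov)
    }
  }
  if (intra_subclonal && nrow(segs) > 0L) {
    i <- sample(nrow(segs), 1L)
    segs$frac_cn[i] <- segs$frac_cn[i] + stats::runif(1, 0.2, 0.45)
  }
  rownames(segs) <- NULL
  segs[, c("sample_id", "chrom", "start", "end", "log2", "n_probes",
           "coverage", "major_cn", "minor_cn", "frac_cn", "category")]
}

sample_bafs <- function(cfg, sample_id, pos, keep_b, loh, purity) {
  n <- length(pos)
  depth <- stats::rpois(n, cfg$baf_depth)
  f <- if (loh) ifelse(keep_b, 1 - (1 - purity) / 2, (1 - purity) / 2) else rep(0.5, n)
  baf <- ifelse(depth > 0, stats::rbinom(n, depth, f) / pmax(depth, 1L), NA_real_)
  out <- data.frame(sample_id = sample_id, chrom = cfg$tp53_locus$chrom,
                    pos = pos, baf = baf, depth = depth, stringsAsFactors = FALSE)
  out[!is.na(out$baf), , drop = FALSE]
}

# ---- main assembly --------------------------------------------------------

build_cohort <- function(cfg) {
  chroms <- names(cfg$chrom_lengths)
  genes <- pdx_gene_table()
  n_cases <- as.integer(cfg$n_cases)
  case_ids <- sprintf("case%03d", seq_len(n_cases))
  cancer <- sample(cfg$cancer_types, n_cases, TRUE)
  has_ht <- stats::runif(n_cases) < cfg$human_tumor_prob
  has_hn <- stats::runif(n_cases) < cfg$human_normal_prob
  n_models <- draw_count(cfg$models_per_case, n_cases)
  centers <- paste0("C", (seq_len(n_cases) - 1L) %% max(1L, cfg$n_centers) + 1L)
  case_wgd <- stats::runif(n_cases) < cfg$p_wgd
  case_loh <- stats::runif(n_cases) <
    ifelse(case_wgd, cfg$p_tp53_loh[["wgd"]], cfg$p_tp53_loh[["no_wgd"]])
  case_dela <- stats::runif(n_cases) <
    ifelse(case_wgd, cfg$p_del_abundant[["wgd"]], cfg$p_del_abundant[["no_wgd"]])

  ## sample tree ------------------------------------------------------------
  srows <- list()
  for (i in seq_len(n_cases)) {
    cid <- case_ids[i]
    if (has_ht[i]) {
      srows[[length(srows) + 1L]] <- data.frame(
        sample_id = paste0(cid, "_HT"), case_id = cid, model_id = NA_character_,
        sample_class = "human_tumor", passage_index = NA_integer_,
        parent_sample_id = NA_character_, cancer_type = cancer[i],
        purity = draw_purity(cfg$purity_human, 1L), center = centers[i],
        stringsAsFactors = FALSE)
    }
    if (has_hn[i]) {
      srows[[length(srows) + 1L]] <- data.frame(
        sample_id = paste0(cid, "_HN"), case_id = cid, model_id = NA_character_,
        sample_class = "human_normal", passage_index = NA_integer_,
        parent_sample_id = NA_character_, cancer_type = cancer[i],
        purity = NA_real_, center = centers[i], stringsAsFactors = FALSE)
    }
    for (m in seq_len(n_models[i])) {
      mid <- sprintf("%s_M%d", cid, m)
      n_pass <- draw_count(cfg$passages_per_model, 1L)
      for (p in seq_len(n_pass) - 1L) {
        parent <- if (p == 0L) {
          if (has_ht[i]) paste0(cid, "_HT") else NA_character_
        } else sprintf("%s_P%d", mid, p - 1L)
        srows[[length(srows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_P%d", mid, p), case_id = cid, model_id = mid,
          sample_class = "pdx", passage_index = p, parent_sample_id = parent,
          cancer_type = cancer[i], purity = draw_purity(cfg$purity_pdx, 1L),
          center = centers[i], stringsAsFactors = FALSE)
      }
    }
  }
  samples <- do.call(rbind, srows)
  rownames(samples) <- NULL
  pdx_models <- unique(samples$model_id[samples$sample_class == "pdx"])

  ## arm spike plan ---------------------------------------------------------
  arm_truth <- data.frame(arm_id = character(), model_id = character(),
                          gene = character(), class = character(),
                          stringsAsFactors = FALSE)
  if (!is.null(cfg$arm_spikes)) {
    for (i in seq_len(nrow(cfg$arm_spikes))) {
      sp <- cfg$arm_spikes[i, ]
      if (!sp$gene %in% genes$gene) {
        stop(sprintf("arm spike gene '%s' not in pdx_gene_table()", sp$gene),
             call. = FALSE)
      }
      pick <- sample(pdx_models, min(sp$n_models, length(pdx_models)))
      arm_truth <- rbind(arm_truth, data.frame(
        arm_id = sp$arm_id, model_id = pick, gene = sp$gene, class = sp$class,
        stringsAsFactors = FALSE))
    }
  }
  # background CNAs are kept clear of the whole druggable gene panel so that
  # gene-level copy-number categories are controlled by spike-ins alone
  protected <- genes

  ## case clone structure & truth mutations ---------------------------------
  truth_mut <- list()
  human_ccf <- list()    # per case: named clone -> ccf
  model_ccf <- list()    # per model: named clone -> ccf after bottleneck
  for (i in seq_len(n_cases)) {
    cid <- case_ids[i]
    tm <- make_case_mutations(cfg, cid, chroms)
    truth_mut[[cid]] <- tm
    ccf <- c(1, stats::runif(cfg$n_subclones, cfg$subclone_ccf[1], cfg$subclone_ccf[2]))
    names(ccf) <- as.character(seq_along(ccf) - 1L)
    human_ccf[[cid]] <- ccf
    mods <- pdx_models[startsWith(pdx_models, paste0(cid, "_"))]
    for (mid in mods) {
      if (cfg$n_subclones > 0L) {
        surv <- stats::runif(cfg$n_subclones) < cfg$bottleneck_prob
        sub <- ccf[-1][surv]
        if (length(sub) > 0L) sub <- sub / sum(sub)
        mc <- c(ccf[1], sub)
      } else mc <- ccf[1]
      model_ccf[[mid]] <- mc
    }
  }

  ## model-private spiked mutations ----------------------------------------
  spike_mut <- list()  # per model: data.frame of clonal spiked mutations
  mut_classes <- c("non_silent_mutation", "variant_whitelist")
  if (nrow(arm_truth) > 0L) arm_truth$variant <- NA_character_
  if (nrow(arm_truth) > 0L) {
    for (i in seq_len(nrow(arm_truth))) {
      at <- arm_truth[i, ]
      if (!at$class %in% mut_classes) next
      g <- genes[genes$gene == at$gene, ]
      pos <- as.integer(g$start + sample(1000:90000, 1L))
      bases <- c("A", "C", "G", "T")
      ref <- sample(bases, 1L)
      row <- data.frame(case_id = sub("_M\\d+$", "", at$model_id), clone = NA_integer_,
                        chrom = g$chrom, pos = pos, ref = ref,
                        alt = sample(setdiff(bases, ref), 1L),
                        variant_type = "snv", gene = at$gene, effect = "non_silent",
                        hotspot = if (at$class == "variant_whitelist")
                          random_hotspot_label(1L) else NA_character_,
                        driver = TRUE, whitelist = TRUE, stringsAsFactors = FALSE)
      spike_mut[[at$model_id]] <- rbind(spike_mut[[at$model_id]], row)
      arm_truth$variant[i] <- row$hotspot
    }
  }

  ## passage-private mutations (inherited down each passage chain) ----------
  private_mut <- list()  # per pdx sample: own private mutations
  pdx_rows <- samples[samples$sample_class == "pdx", , drop = FALSE]
  for (j in seq_len(nrow(pdx_rows))) {
    sid <- pdx_rows$sample_id[j]
    k <- cfg$passage_private_mutations
    if (k > 0L) {
      pm <- make_case_mutations(
        utils::modifyList(cfg, list(n_clonal_mutations = k, n_subclones = 0L)),
        pdx_rows$case_id[j], chroms)
      pm$driver <- FALSE
      pm$hotspot <- NA_character_
      private_mut[[sid]] <- pm
    }
  }

  ## observed mutation calls -------------------------------------------------
  call_rows <- list()
  tumor <- samples[samples$sample_class != "human_normal", , drop = FALSE]
  for (j in seq_len(nrow(tumor))) {
    s <- tumor[j, ]
    cid <- s$case_id
    has_normal <- has_hn[match(cid, case_ids)]
    tm <- truth_mut[[cid]]
    if (s$sample_class == "human_tumor") {
      ccf <- unname(human_ccf[[cid]][as.character(tm$clone)])
      obs <- observe_calls(cfg, s$sample_id, tm, ccf, s$purity, has_normal)
      call_rows[[length(call_rows) + 1L]] <- obs
    } else {
      mc <- model_ccf[[s$model_id]]
      ccf <- unname(mc[as.character(tm$clone)])
      ccf[is.na(ccf)] <- 0
      extra <- spike_mut[[s$model_id]]
      chain <- samples$sample_id[samples$model_id %in% s$model_id &
                                 samples$passage_index <= s$passage_index]
      for (anc in chain) extra <- rbind(extra, private_mut[[anc]])
      muts <- tm
      ccf_all <- ccf
      if (!is.null(extra) && nrow(extra) > 0L) {
        muts <- rbind(tm, extra[, names(tm)])
        ccf_all <- c(ccf, rep(1, nrow(extra)))
      }
      obs <- observe_calls(cfg, s$sample_id, muts, ccf_all, s$purity, has_normal)
      call_rows[[length(call_rows) + 1L]] <- obs
    }
    call_rows[[length(call_rows) + 1L]] <-
      false_positive_calls(cfg, s$sample_id, chroms, has_normal)
  }
  mutations <- do.call(rbind, call_rows)
  if (is.null(mutations)) {
    mutations <- data.frame(sample_id = character(), chrom = character(),
                            pos = integer(), ref = character(), alt = character(),
                            variant_type = character(), gene = character(),
                            effect = character(), hotspot = character(),
                            driver = logical(), callers = character(),
                            t_depth = integer(), t_alt = integer(),
                            n_depth = integer(), n_alt = integer(),
                            whitelist = logical(), stringsAsFactors = FALSE)
  }
  rownames(mutations) <- NULL

  ## germline SNP panel ------------------------------------------------------
  n_loci <- as.integer(cfg$n_snp_loci)
  loci <- data.frame(
    chrom = sample(chroms, n_loci, TRUE),
    pos = as.integer(floor(stats::runif(n_loci, 1, 9e7))),
    pop_af = stats::runif(n_loci, cfg$snp_af_range[1], cfg$snp_af_range[2]),
    stringsAsFactors = FALSE)
  geno <- matrix(stats::rbinom(n_loci * n_cases, 2L, rep(loci$pop_af, n_cases)),
                 nrow = n_loci, dimnames = list(NULL, case_ids))
  n_samp <- nrow(samples)
  depth_m <- matrix(stats::rpois(n_loci * n_samp, cfg$snp_depth_mean),
                    nrow = n_loci, dimnames = list(NULL, samples$sample_id))
  vaf_m <- matrix(NA_real_, n_loci, n_samp,
                  dimnames = list(NULL, samples$sample_id))
  for (j in seq_len(n_samp)) {
    g <- geno[, samples$case_id[j]]
    d <- depth_m[, j]
    v <- stats::rbinom(n_loci, d, g / 2) / pmax(d, 1L)
    v[d == 0L] <- NA_real_
    vaf_m[, j] <- v
  }

  ## copy-number segments and BAFs ------------------------------------------
  seg_rows <- list()
  baf_rows <- list()
  flag_rows <- list()
  w <- cfg$tp53_locus
  half <- cfg$loh_window_bp / 2
  mid_tp53 <- (w$start + w$end) / 2
  for (i in seq_len(n_cases)) {
    cid <- case_ids[i]
    layout <- case_segment_layout(cfg, case_dela[i], protected)
    baf_pos <- sort(as.integer(stats::runif(cfg$n_baf_snps,
                                            max(1, mid_tp53 - half),
                                            mid_tp53 + half)))
    keep_b <- stats::runif(cfg$n_baf_snps) < 0.5
    ts <- tumor[tumor$case_id == cid, , drop = FALSE]
    for (j in seq_len(nrow(ts))) {
      s <- ts[j, ]
      ov <- NULL
      if (!is.na(s$model_id) && nrow(arm_truth) > 0L) {
        cls <- arm_truth[arm_truth$model_id %in% s$model_id &
                         arm_truth$class %in% c("amplification", "deletion"), ,
                         drop = FALSE]
        if (nrow(cls) > 0L) {
          ov <- merge(cls, genes, by = "gene")[, c("chrom", "start", "end", "class")]
        }
      }
      intra <- stats::runif(1) < cfg$p_intra_subclonal
      priv <- stats::runif(1) < cfg$p_private_segment
      seg_rows[[length(seg_rows) + 1L]] <- sample_segments(
        cfg, s$sample_id, layout, case_wgd[i], case_loh[i], s$purity,
        intra, priv, ov)
      baf_rows[[length(baf_rows) + 1L]] <- sample_bafs(
        cfg, s$sample_id, baf_pos, keep_b, case_loh[i], s$purity)
      flag_rows[[length(flag_rows) + 1L]] <- data.frame(
        sample_id = s$sample_id, case_id = cid, wgd = case_wgd[i],
        tp53_loh = case_loh[i], del_abundant = case_dela[i],
        intra_subclonal = intra, stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, seg_rows)
  rownames(segments) <- NULL
  bafs <- do.call(rbind, baf_rows)
  rownames(bafs) <- NULL
  sample_flags <- do.call(rbind, flag_rows)
  rownames(sample_flags) <- NULL

  ## expression --------------------------------------------------------------
  n_genes <- as.integer(cfg$n_genes)
  real <- genes$gene[seq_len(min(nrow(genes), n_genes))]
  n_fill <- n_genes - length(real)
  gene_ids <- c(real, sprintf("G%04d", seq_len(max(0L, n_fill))))
  filler <- setdiff(gene_ids, real)
  k_grp <- as.integer(cfg$n_expression_groups)
  sig_need <- k_grp * cfg$signature_size
  if (length(filler) < sig_need) {
    stop("n_genes too small for the requested group signatures", call. = FALSE)
  }
  sig_genes <- split(sample(filler, sig_need),
                     rep(seq_len(k_grp), each = cfg$signature_size))
  case_grp <- sample.int(k_grp, n_cases, TRUE)
  baseline <- stats::rnorm(n_genes, cfg$baseline_mean, cfg$baseline_sd)
  offs <- matrix(stats::rnorm(n_genes * max(1L, cfg$n_centers), 0, cfg$center_offset_sd),
                 nrow = n_genes,
                 dimnames = list(gene_ids, paste0("C", seq_len(max(1L, cfg$n_centers)))))
  expr_samples <- tumor$sample_id
  vals <- matrix(NA_real_, n_genes, length(expr_samples),
                 dimnames = list(gene_ids, expr_samples))
  grp_rows <- list()
  for (j in seq_along(expr_samples)) {
    s <- tumor[j, ]
    grp <- case_grp[match(s$case_id, case_ids)]
    if (s$sample_class == "pdx" && k_grp > 1L && stats::runif(1) < cfg$p_cluster_shift) {
      grp <- sample(setdiff(seq_len(k_grp), grp), 1L)
    }
    x <- baseline + offs[, s$center] + stats::rnorm(n_genes, 0, cfg$noise_sd)
    x[match(sig_genes[[grp]], gene_ids)] <-
      x[match(sig_genes[[grp]], gene_ids)] + cfg$group_effect * cfg$noise_sd
    vals[, j] <- x
    grp_rows[[j]] <- data.frame(sample_id = s$sample_id,
                                model_id = s$model_id, group = grp,
                                stringsAsFactors = FALSE)
  }
  expression_groups <- do.call(rbind, grp_rows)
  ## spike-driven expression shifts on target genes
  if (nrow(arm_truth) > 0L) {
    boost <- c(non_silent_mutation = 1.5, variant_whitelist = 1.5,
               amplification = 2, deletion = -2, fusion = 1.5)
    for (i in seq_len(nrow(arm_truth))) {
      at <- arm_truth[i, ]
      if (!at$gene %in% gene_ids) next
      sids <- tumor$sample_id[tumor$model_id %in% at$model_id]
      sids <- intersect(sids, colnames(vals))
      vals[at$gene, sids] <- vals[at$gene, sids] + boost[[at$class]]
    }
  }
  vals <- pmax(vals, 0)

  ## fusions -----------------------------------------------------------------
  fus_rows <- list()
  pdx_ids <- samples$sample_id[samples$sample_class == "pdx"]
  if (cfg$n_decoy_fusions > 0L && length(pdx_ids) > 0L) {
    nd <- cfg$n_decoy_fusions
    low_ffpm <- stats::runif(nd) < 0.5
    fus_rows[[1L]] <- data.frame(
      sample_id = sample(pdx_ids, nd, TRUE),
      gene5 = sample(bg_gene_pool(), nd, TRUE),
      gene3 = sample(bg_gene_pool(), nd, TRUE),
      in_frame = stats::runif(nd) < 0.5,
      ffpm = ifelse(low_ffpm, stats::runif(nd, 0.01, 0.1), stats::runif(nd, 0.2, 1)),
      annotation_tags = ifelse(low_ffpm, "", "Greger_Normal"),
      stringsAsFactors = FALSE)
  }
  if (nrow(arm_truth) > 0L) {
    ft <- arm_truth[arm_truth$class == "fusion", , drop = FALSE]
    for (i in seq_len(nrow(ft))) {
      sids <- samples$sample_id[samples$model_id %in% ft$model_id[i]]
      if (length(sids) == 0L) next
      fus_rows[[length(fus_rows) + 1L]] <- data.frame(
        sample_id = sids, gene5 = ft$gene[i],
        gene3 = sample(bg_gene_pool(), 1L),
        in_frame = TRUE, ffpm = stats::runif(length(sids), 0.5, 3),
        annotation_tags = "", stringsAsFactors = FALSE)
    }
  }
  fusions <- if (length(fus_rows) > 0L) do.call(rbind, fus_rows) else
    data.frame(sample_id = character(), gene5 = character(), gene3 = character(),
               in_frame = logical(), ffpm = numeric(), annotation_tags = character(),
               stringsAsFactors = FALSE)
  rownames(fusions) <- NULL

  ## truth tables ------------------------------------------------------------
  truth_mut_df <- do.call(rbind, truth_mut)
  rownames(truth_mut_df) <- NULL
  ccf_rows <- list()
  for (cid in case_ids) {
    cc <- human_ccf[[cid]]
    ccf_rows[[length(ccf_rows) + 1L]] <- data.frame(
      unit = cid, scope = "case", clone = names(cc), ccf = unname(cc),
      stringsAsFactors = FALSE)
  }
  for (mid in names(model_ccf)) {
    mc <- model_ccf[[mid]]
    ccf_rows[[length(ccf_rows) + 1L]] <- data.frame(
      unit = mid, scope = "model", clone = names(mc), ccf = unname(mc),
      stringsAsFactors = FALSE)
  }
  truth <- list(
    mutations = truth_mut_df,
    clone_ccf = do.call(rbind, ccf_rows),
    sample_flags = sample_flags,
    expression_groups = expression_groups,
    arm_truth = arm_truth,
    anomalies = data.frame(type = character(), sample_a = character(),
                           sample_b = character(), frac = numeric(),
                           stringsAsFactors = FALSE))

  structure(list(samples = samples, mutations = mutations,
                 snp = list(loci = loci, vaf = vaf_m, depth = depth_m),
                 segments = segments, bafs = bafs,
                 expression = vals, fusions = fusions,
                 truth = truth, config = cfg),
            class = "pdx_cohort")
}

#' @export
print.pdx_cohort <- function(x, ...) {
  cat("<pdx_cohort>\n")
  cat(sprintf("  %d samples (%d PDX) in %d cases; %d mutation calls\n",
              nrow(x$samples), sum(x$samples$sample_class == "pdx"),
              length(unique(x$samples$case_id)), nrow(x$mutations)))
  cat(sprintf("  %d SNP loci; %d CN segments; %d x %d expression matrix; %d fusions\n",
              nrow(x$snp$loci), nrow(x$segments),
              nrow(x$expression), ncol(x$expression), nrow(x$fusions)))
  invisible(x)
}
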