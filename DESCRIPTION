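Package: pdxkit
Title: Quality Control, Variant Filtering, and Lineage Analysis for Patient-Derived Xenograft Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the computational layer used in
    pan-cancer patient-derived xenograft (PDX) characterization: germline SNP
    VAF concordance checks for sample swap/contamination detection, consensus
    and tumor-only somatic variant filter cascades with PDX-specific
    false-positive removal, Jaccard mutational similarity within and across
    PDX model lineages, copy-number categorization with whole-genome
    duplication and TP53 loss-of-heterozygosity calling plus chi-squared
    association testing, consensus clustering of expression with a
    cluster-shift score, cis/trans mutation-expression testing, and
    basket-trial treatment-arm matching with a passage-depth score. Includes a
    synthetic PDX cohort generator with known ground truth (lineage trees,
    clonal bottlenecks, purity-dependent read counts, planted anomalies) that
    stands in for restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
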