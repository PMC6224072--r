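Package: repairscan
Title: Zygosity- and Rarity-Based Variant Selection for Functional
    Repair-Defect Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects candidate pathogenic variants in targeted sequencing
    panels by allele zygosity (variant allele fraction) and population
    rarity (minor allele frequency), and links pathway mutation status to
    a cellular drug-sensitivity endpoint (mitomycin C IC50).  Provides
    post-calling QC filters, Wilcoxon rank-sum association with a
    positive-predictive-value summary, length-matched random gene-set and
    nearest-gene controls, an all-pathway screen with correlation-based
    redundancy pruning, a tumor-suppressor versus oncogene zygosity/LOH
    enrichment analysis, and synthetic cell-line panel and tumor cohort
    generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    vcfR,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
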