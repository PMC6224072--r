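# Synthetic cell-line panels and tumor cohorts with known ground truth.
# The panel generator emulates a 29-sample targeted-capture panel with a
# bimodal VAF distribution (heterozygous mode near 0.5, homozygous mode
# near 0.95), population-MAF annotations spanning the 1% rarity
# criterion, and a planted repair-defective subset carrying homozygous
# rare variants in a designated pathway whose members are hypersensitive
# to the drug (lower IC50).  The tumor generator produces a
# purity-confounded trimodal VAF distribution with class-biased LOH.

#' Canonical interstrand-crosslink repair (FA/HR) gene symbols
#'
#' Default planted-pathway members for the panel generator: twenty
#' Fanconi anemia / homologous recombination genes.
#' @export
FA_HR_GENES <- c("FANCA", "FANCB", "FANCC", "FANCD2", "FANCE", "FANCF",
                 "FANCG", "FANCI", "FANCL", "FANCM", "BRCA1", "BRCA2",
                 "BRIP1", "PALB2", "RAD51", "RAD51C", "SLX4", "ERCC4",
                 "UBE2T", "XRCC2")

#' Cell-line panel generator specification
#'
#' Defaults describe the emulated study conditions: 29 cell lines, a
#' 556-gene capture, ten repair-defective lines each carrying at least
#' one homozygous rare variant in the planted pathway, heterozygous and
#' homozygous VAF modes at 0.5 (sd 0.07) and 0.95 (sd 0.04), 70% of
#' variants SNP-annotated with a common/rare MAF mixture, ~150 variants
#' per sample, and defective IC50 one natural-log unit below proficient.
#' `decoy_het_rate` is the mean number of heterozygous pathway-gene
#' variants given to each proficient sample; these carry a mixture of
#' common and rare/absent MAF annotations, so some survive a pure MAF
#' filter and only a VAF (zygosity) filter removes them.
#'
#' @param n_samples number of cell lines.
#' @param n_genes total genes on the capture (pathway included).
#' @param pathway_genes planted-pathway gene symbols.
#' @param n_defective number of repair-defective lines.
#' @param het_vaf_mean,het_vaf_sd heterozygous VAF mode (truncated
#'   normal on \[0, 1\]).
#' @param hom_vaf_mean,hom_vaf_sd homozygous VAF mode.
#' @param hom_fraction fraction of background variants that are
#'   homozygous.
#' @param snp_fraction fraction of variants carrying a population MAF.
#' @param maf_common_prob probability a SNP draws from the common
#'   component (uniform 0.05-0.5) rather than the rare tail
#'   (log-uniform 1e-4 to 0.01).
#' @param variants_per_sample mean background variants per sample.
#' @param ic50_defective,ic50_proficient `c(meanlog, sdlog)` of the
#'   lognormal IC50 distributions (arbitrary concentration units).
#' @param decoy_het_rate mean decoy heterozygous pathway variants per
#'   proficient sample.
#' @param depth_mean mean sequencing depth (negative binomial).
#' @param seed integer seed.
#' @return object of class `panel_spec`.
#' @export
panel_spec <- function(n_samples = 29L, n_genes = 556L,
                       pathway_genes = FA_HR_GENES,
                       n_defective = 10L,
                       het_vaf_mean = 0.5, het_vaf_sd = 0.07,
                       hom_vaf_mean = 0.95, hom_vaf_sd = 0.04,
                       hom_fraction = 0.25,
                       snp_fraction = 0.7,
                       maf_common_prob = 0.7,
                       variants_per_sample = 150,
                       ic50_defective = c(meanlog = log(3) - 1,
                                          sdlog = 0.4),
                       ic50_proficient = c(meanlog = log(3),
                                           sdlog = 0.4),
                       decoy_het_rate = 1.5,
                       depth_mean = 247,
                       seed = 1L) {
  stopifnot(n_defective <= n_samples,
            hom_vaf_mean > het_vaf_mean,
            hom_fraction >= 0, hom_fraction <= 1,
            snp_fraction >= 0, snp_fraction <= 1,
            length(pathway_genes) >= 1L,
            n_genes > length(pathway_genes))
  structure(as.list(environment()), class = "panel_spec")
}

#' Tumor cohort generator specification
#'
#' Defaults: 56 tumors with purity uniform on \[0.3, 0.9\], six
#' tumor-suppressor and ten oncogene symbols, per-gene-per-sample LOH
#' probability 0.5 (TSG) versus 0.1 (oncogene), and germline variants
#' that are homozygous with probability `germline_hom_fraction`.
#' Somatic VAF follows the purity mixture
#' `(u * c_v + (1 - u) * g_v) / (u * c_t + (1 - u) * 2)` with germline
#' copies `g_v`, tumor total copies `c_t` and tumor variant copies
#' `c_v`; under LOH `c_v = c_t = 1`.
#'
#' @param n_samples number of tumors.
#' @param purity_range uniform purity interval within (0, 1\].
#' @param tsg_genes,og_genes tumor-suppressor and oncogene symbols.
#' @param loh_prob_tsg,loh_prob_og per-gene-per-sample LOH probability.
#' @param var_rate_tsg,var_rate_og mean variants per gene per sample.
#' @param germline_hom_fraction probability a germline variant is
#'   homozygous.
#' @param depth_mean mean sequencing depth.
#' @param seed integer seed.
#' @return object of class `tumor_spec`.
#' @export
tumor_spec <- function(n_samples = 56L,
                       purity_range = c(0.3, 0.9),
                       tsg_genes = c("TP53", "CDKN2A", "PTEN", "NOTCH1",
                                     "FAT1", "SMAD4"),
                       og_genes = c("PIK3CA", "EGFR", "CCND1", "MYC",
                                    "HRAS", "FGFR1", "FGFR3", "ERBB2",
                                    "MET", "AKT1"),
                       loh_prob_tsg = 0.5, loh_prob_og = 0.1,
                       var_rate_tsg = 0.2, var_rate_og = 0.05,
                       germline_hom_fraction = 0.15,
                       depth_mean = 247,
                       seed = 1L) {
  stopifnot(purity_range[1] > 0, purity_range[2] <= 1,
            purity_range[1] <= purity_range[2],
            loh_prob_tsg >= 0, loh_prob_tsg <= 1,
            loh_prob_og >= 0, loh_prob_og <= 1)
  structure(as.list(environment()), class = "tumor_spec")
}

# truncated normal on [0, 1] by rejection
rtnorm01 <- function(n, mean, sd) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < 0 | out > 1)
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < 0 | out > 1)
  }
  out
}

# gene annotation with log-uniform lengths (500-10,000 bases), genes
# spread over 22 chromosomes with per-chromosome order indices and
# non-overlapping start coordinates
make_annotation <- function(genes) {
  n <- length(genes)
  len <- round(exp(runif(n, log(500), log(10000))))
  chrom <- as.character(rep_len(1:22, n))
  ord <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  start <- unsplit(lapply(split(len, chrom), function(l) {
    cumsum(c(1, utils::head(l + 1000L, -1L)))
  }), chrom)
  ann <- data.frame(gene = genes, length = len, chrom = chrom,
                    order_index = as.integer(ord),
                    class = NA_character_, stringsAsFactors = FALSE)
  attr(ann, "gene_start") <- setNames(start, genes)
  ann
}

draw_maf <- function(n, snp_fraction, common_prob) {
  is_snp <- runif(n) < snp_fraction
  common <- runif(n) < common_prob
  maf <- ifelse(common, runif(n, 0.05, 0.5),
                exp(runif(n, log(1e-4), log(0.01))))
  ifelse(is_snp, maf, NA_real_)
}

BASES <- c("A", "C", "G", "T")

# Assemble variant rows; zygosity in {"het","hom"} picks the VAF mode.
make_panel_variants <- function(sample_id, gene, zygosity, spec,
                                annotation, maf, consequence, kind) {
  n <- length(gene)
  if (n == 0L) return(NULL)
  true_vaf <- ifelse(zygosity == "hom",
                     rtnorm01(n, spec$hom_vaf_mean, spec$hom_vaf_sd),
                     rtnorm01(n, spec$het_vaf_mean, spec$het_vaf_sd))
  depth <- pmax(12L, rnbinom(n, size = 10, mu = spec$depth_mean))
  alt_reads <- pmin(depth, pmax(1L, rbinom(n, depth, true_vaf)))
  start <- attr(annotation, "gene_start")[gene]
  glen <- setNames(annotation$length, annotation$gene)[gene]
  pos <- as.integer(start + floor(runif(n) * glen))
  chrom <- setNames(annotation$chrom, annotation$gene)[gene]
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), "")
  ins <- kind == "INS"; del <- kind == "DEL"
  alt[ins] <- paste0(ref[ins], "T")
  ref[del] <- paste0(ref[del], "T")
  alt[del] <- substr(ref[del], 1L, 1L)
  data.frame(sample_id = sample_id, gene = gene, chrom = unname(chrom),
             pos = pos, ref = unname(ref), alt = unname(alt),
             kind = kind, depth = depth, alt_reads = alt_reads,
             vaf = alt_reads / depth, maf = maf,
             consequence = consequence,
             score = runif(n), loh = NA,
             stringsAsFactors = FALSE)
}

sample_consequences <- function(kind) {
  n <- length(kind)
  out <- character(n)
  snv <- kind == "SNV"
  out[snv] <- sample(c("nonsynonymous", "stopgain", "stoploss",
                       "splice_essential", "synonymous"),
                     sum(snv), replace = TRUE,
                     prob = c(0.58, 0.05, 0.01, 0.04, 0.32))
  out[!snv] <- sample(c("frameshift", "nonframeshift_indel"),
                      sum(!snv), replace = TRUE, prob = c(0.7, 0.3))
  out
}

#' Simulate a cell-line panel with a planted repair defect
#'
#' Each defective sample carries at least one homozygous variant (from
#' the high-VAF mode) with an absent or rare (< 1%) MAF in a planted
#' pathway gene, and draws its IC50 from the lower (sensitive)
#' lognormal.  Proficient samples receive heterozygous decoy variants
#' in pathway genes at `decoy_het_rate`, and draw IC50 from the higher
#' distribution.  Background variants (mixture of het/hom, SNP/non-SNP)
#' are spread over the non-pathway genes, length-weighted.  Identical
#' seeds give identical output.
#'
#' @param spec a [panel_spec()].
#' @return object of class `panel_sim`: list with `variants`,
#'   `phenotypes`, `annotation`, `pathway` (a [gene_set()]) and `truth`
#'   (`$samples`: per-sample defect labels; `$variants`: per-variant
#'   zygosity / planted / decoy labels aligned to `variants` rows).
#' @export
simulate_panel <- function(spec = panel_spec()) {
  simulate_panel_impl(spec, null_panel = FALSE)
}

#' Simulate a null panel (no defect / IC50 linkage)
#'
#' As [simulate_panel()], but every sample draws IC50 from the
#' proficient distribution and pathway genes receive ordinary
#' background variants with no zygosity or rarity bias: mutation
#' assignment of any gene set is independent of the IC50 ranking.
#'
#' @param spec a [panel_spec()]; `n_defective` is ignored.
#' @return object of class `panel_sim` (all truth labels proficient).
#' @export
simulate_null_panel <- function(spec = panel_spec()) {
  simulate_panel_impl(spec, null_panel = TRUE)
}

simulate_panel_impl <- function(spec, null_panel) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  ids <- sprintf("CL%02d", seq_len(spec$n_samples))
  background_genes <- sprintf("GENE%04d",
                              seq_len(spec$n_genes -
                                        length(spec$pathway_genes)))
  annotation <- make_annotation(c(spec$pathway_genes, background_genes))
  defective <- rep(FALSE, spec$n_samples)
  if (!null_panel) {
    defective[sample.int(spec$n_samples, spec$n_defective)] <- TRUE
  }
  ic50 <- ifelse(defective,
                 rlnorm(spec$n_samples, spec$ic50_defective[["meanlog"]],
                        spec$ic50_defective[["sdlog"]]),
                 rlnorm(spec$n_samples,
                        spec$ic50_proficient[["meanlog"]],
                        spec$ic50_proficient[["sdlog"]]))
  phenotypes <- data.frame(sample_id = ids, ic50 = ic50,
                           stringsAsFactors = FALSE)

  bg_pool <- if (null_panel) annotation$gene else background_genes
  bg_weight <- setNames(annotation$length, annotation$gene)[bg_pool]
  parts <- list(); labels <- list()
  for (i in seq_len(spec$n_samples)) {
    n_bg <- rpois(1L, spec$variants_per_sample)
    if (n_bg > 0L) {
      genes <- sample(bg_pool, n_bg, replace = TRUE, prob = bg_weight)
      zyg <- ifelse(runif(n_bg) < spec$hom_fraction, "hom", "het")
      kind <- sample(VARIANT_KINDS, n_bg, replace = TRUE,
                     prob = c(0.93, 0.03, 0.04))
      part <- make_panel_variants(ids[i], genes, zyg, spec, annotation,
                                  draw_maf(n_bg, spec$snp_fraction,
                                           spec$maf_common_prob),
                                  sample_consequences(kind), kind)
      parts[[length(parts) + 1L]] <- part
      labels[[length(labels) + 1L]] <-
        data.frame(zygosity = zyg, planted = FALSE, decoy = FALSE,
                   stringsAsFactors = FALSE)
    }
    if (null_panel) next
    if (defective[i]) {
      n_pl <- 1L + rpois(1L, 0.5)
      genes <- sample(spec$pathway_genes, n_pl, replace = TRUE)
      maf <- ifelse(runif(n_pl) < 0.5, NA_real_,
                    exp(runif(n_pl, log(1e-4), log(0.009))))
      cons <- sample(c("nonsynonymous", "stopgain", "splice_essential"),
                     n_pl, replace = TRUE, prob = c(0.7, 0.2, 0.1))
      part <- make_panel_variants(ids[i], genes, rep("hom", n_pl), spec,
                                  annotation, maf, cons,
                                  rep("SNV", n_pl))
      parts[[length(parts) + 1L]] <- part
      labels[[length(labels) + 1L]] <-
        data.frame(zygosity = rep("hom", n_pl), planted = TRUE,
                   decoy = FALSE, stringsAsFactors = FALSE)
    } else if (spec$decoy_het_rate > 0) {
      n_d <- rpois(1L, spec$decoy_het_rate)
      if (n_d > 0L) {
        genes <- sample(spec$pathway_genes, n_d, replace = TRUE)
        u <- runif(n_d)
        maf <- ifelse(u < 0.5, runif(n_d, 0.05, 0.5),
                      ifelse(u < 0.75,
                             exp(runif(n_d, log(1e-4), log(0.009))),
                             NA_real_))
        part <- make_panel_variants(ids[i], genes, rep("het", n_d),
                                    spec, annotation,
                                    maf, rep("nonsynonymous", n_d),
                                    rep("SNV", n_d))
        parts[[length(parts) + 1L]] <- part
        labels[[length(labels) + 1L]] <-
          data.frame(zygosity = rep("het", n_d), planted = FALSE,
                     decoy = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  variants <- as_variant_table(do.call(rbind, parts))
  truth_variants <- do.call(rbind, labels)
  rownames(truth_variants) <- NULL
  pathway <- gene_set("planted_pathway", spec$pathway_genes,
                      sum(annotation$length[annotation$gene %in%
                                              spec$pathway_genes]))
  structure(list(variants = variants, phenotypes = phenotypes,
                 annotation = annotation, pathway = pathway,
                 truth = list(
                   samples = data.frame(sample_id = ids,
                                        defective = defective,
                                        stringsAsFactors = FALSE),
                   variants = truth_variants)),
            class = "panel_sim")
}

#' @export
print.panel_sim <- function(x, ...) {
  cat("Synthetic cell-line panel: ", nrow(x$phenotypes), " samples, ",
      nrow(x$variants), " variants, ",
      sum(x$truth$samples$defective), " defective\n", sep = "")
  invisible(x)
}

#' VAF histogram of a simulated panel
#' @param x a `panel_sim` object.
#' @param breaks histogram breaks.
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.panel_sim <- function(x, breaks = 50, ...) {
  hist(x$variants$vaf, breaks = breaks, main = "Pooled VAF distribution",
       xlab = "variant allele fraction", ...)
  invisible(x)
}

# Purity-mixture VAF: u purity, c_v tumor variant copies, c_t tumor
# total copies, g_v germline variant copies (germline total = 2).
tumor_vaf <- function(u, c_v, c_t, g_v) {
  (u * c_v + (1 - u) * g_v) / (u * c_t + (1 - u) * 2)
}

#' Simulate a tumor cohort with purity-confounded VAF and biased LOH
#'
#' Per sample a purity is drawn; per gene an LOH event occurs with its
#' class probability; germline variants (heterozygous or homozygous)
#' get VAF from the purity mixture, producing the characteristic
#' trimodal pooled distribution (heterozygous near 0.5, LOH-shifted
#' intermediate at `1 / (2 - u)`, homozygous near 1).  The `loh` flag
#' is set truthfully from the simulated event.
#'
#' @param spec a [tumor_spec()].
#' @return object of class `tumor_sim`: list with `variants`, `classes`
#'   (gene/class table), `purity` (named per-sample vector) and `truth`
#'   (per-variant germline zygosity and LOH labels).
#' @export
simulate_tumors <- function(spec = tumor_spec()) {
  stopifnot(inherits(spec, "tumor_spec"))
  set.seed(spec$seed)
  ids <- sprintf("T%03d", seq_len(spec$n_samples))
  genes <- c(spec$tsg_genes, spec$og_genes)
  classes <- data.frame(gene = genes,
                        class = rep(c("TSG", "oncogene"),
                                    c(length(spec$tsg_genes),
                                      length(spec$og_genes))),
                        stringsAsFactors = FALSE)
  annotation <- make_annotation(genes)
  purity <- setNames(runif(spec$n_samples, spec$purity_range[1],
                           spec$purity_range[2]), ids)
  loh_prob <- ifelse(classes$class == "TSG", spec$loh_prob_tsg,
                     spec$loh_prob_og)
  var_rate <- ifelse(classes$class == "TSG", spec$var_rate_tsg,
                     spec$var_rate_og)
  parts <- list(); truth <- list()
  for (i in seq_len(spec$n_samples)) {
    u <- purity[[i]]
    loh_gene <- runif(length(genes)) < loh_prob
    n_var <- rpois(length(genes), var_rate)
    if (sum(n_var) == 0L) next
    gene_v <- rep(genes, n_var)
    loh_v <- rep(loh_gene, n_var)
    n <- length(gene_v)
    g_v <- ifelse(runif(n) < spec$germline_hom_fraction, 2L, 1L)
    c_t <- ifelse(loh_v, 1L, 2L)
    c_v <- ifelse(loh_v, 1L, g_v)
    true_vaf <- tumor_vaf(u, c_v, c_t, g_v)
    depth <- pmax(12L, rnbinom(n, size = 10, mu = spec$depth_mean))
    alt_reads <- pmin(depth, pmax(1L, rbinom(n, depth, true_vaf)))
    start <- attr(annotation, "gene_start")[gene_v]
    glen <- setNames(annotation$length, annotation$gene)[gene_v]
    ref <- sample(BASES, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), "")
    parts[[length(parts) + 1L]] <- data.frame(
      sample_id = ids[i], gene = gene_v,
      chrom = unname(setNames(annotation$chrom,
                              annotation$gene)[gene_v]),
      pos = as.integer(start + floor(runif(n) * glen)),
      ref = unname(ref), alt = unname(alt), kind = "SNV",
      depth = depth, alt_reads = alt_reads, vaf = alt_reads / depth,
      maf = ifelse(runif(n) < 0.5,
                   exp(runif(n, log(1e-4), log(0.009))), NA_real_),
      consequence = sample(c("nonsynonymous", "stopgain"), n,
                           replace = TRUE, prob = c(0.9, 0.1)),
      score = runif(n), loh = loh_v, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      sample_id = ids[i], gene = gene_v,
      germline = ifelse(g_v == 2L, "hom", "het"),
      loh = loh_v, true_vaf = true_vaf, stringsAsFactors = FALSE)
  }
  variants <- as_variant_table(do.call(rbind, parts))
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(variants = variants, classes = classes,
                 purity = purity, truth = truth),
            class = "tumor_sim")
}

#' @export
print.tumor_sim <- function(x, ...) {
  cat("Synthetic tumor cohort: ", length(x$purity), " samples, ",
      nrow(x$variants), " variants (",
      sum(x$variants$loh), " with LOH)\n", sep = "")
  invisible(x)
}

#' Build a pathway collection around a planted pathway
#'
#' Returns the planted pathway plus `n_decoys` random pathways drawn
#' from the non-pathway genes of the annotation (sizes uniform on
#' `size_range`), mimicking a pathway-database screen in which exactly
#' one pathway carries the true signal.
#'
#' @param annotation gene annotation table.
#' @param pathway the planted [gene_set()].
#' @param n_decoys number of decoy pathways.
#' @param size_range integer range of decoy pathway sizes.
#' @param seed optional integer seed.
#' @return named list of [gene_set()] objects (planted pathway first).
#' @export
simulate_pathway_collection <- function(annotation, pathway,
                                        n_decoys = 49L,
                                        size_range = c(10L, 60L),
                                        seed = NULL) {
  annotation <- as_gene_annotation(annotation)
  if (!is.null(seed)) set.seed(seed)
  pool <- setdiff(annotation$gene, pathway$genes)
  lens <- setNames(annotation$length, annotation$gene)
  decoys <- lapply(seq_len(n_decoys), function(i) {
    k <- sample(seq(size_range[1], size_range[2]), 1L)
    genes <- sample(pool, min(k, length(pool)))
    gene_set(sprintf("decoy_pathway_%03d", i), genes,
             sum(lens[genes]))
  })
  out <- c(list(pathway), decoys)
  setNames(out, vapply(out, `[[`, "", "name"))
}
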