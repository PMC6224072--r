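# Tumor-suppressor versus oncogene zygosity enrichment: per-gene LOH
# tallies compared with the rank-sum test, and the pooled 2x2
# homozygous/heterozygous Fisher exact test.  Tumor-suppressor
# inactivation typically requires loss of both alleles (hence LOH and
# homozygous variants); oncogene activation does not.

#' Tally LOH and homozygosity per gene and class
#'
#' For each gene carrying a `TSG` or `oncogene` class label, counts the
#' number of distinct samples with at least one LOH-flagged variant
#' (`n_samples_loh`), the number of variant records (`n_variants`) and
#' the number of homozygous records (`n_homozygous`).  A record is
#' homozygous when its `loh` flag is `TRUE` *or* its VAF is at least
#' `hom_vaf` (germline homozygous variants sit near VAF 1 irrespective
#' of tumor purity and carry no LOH flag); records with `loh = NA` fall
#' back to the VAF rule alone.  Genes of a class without any variants
#' are kept as zero rows.  Variants in unclassified genes are excluded
#' with a warning.
#'
#' @param variants tumor-cohort variant table with `loh` flags.
#' @param classes data.frame with columns `gene`, `class` (`TSG` /
#'   `oncogene`).
#' @param hom_vaf VAF at or above which a variant counts as homozygous
#'   (default 0.8).
#' @return data.frame with columns `gene`, `class`, `n_samples_loh`,
#'   `n_variants`, `n_homozygous`.
#' @export
tally_by_class <- function(variants, classes, hom_vaf = 0.8) {
  variants <- as_variant_table(variants)
  stopifnot(is.data.frame(classes),
            all(c("gene", "class") %in% names(classes)))
  classes <- data.frame(gene = as.character(classes$gene),
                        class = as.character(classes$class),
                        stringsAsFactors = FALSE)
  bad <- setdiff(classes$class, c("TSG", "oncogene"))
  if (length(bad) > 0L) {
    stop("unknown gene class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unclassified <- setdiff(unique(variants$gene), classes$gene)
  if (length(unclassified) > 0L) {
    warning("excluding variant(s) in unclassified gene(s): ",
            paste(unclassified, collapse = ", "))
    variants <- variants[variants$gene %in% classes$gene, , drop = FALSE]
  }
  hom <- (!is.na(variants$loh) & variants$loh) | variants$vaf >= hom_vaf
  loh <- !is.na(variants$loh) & variants$loh
  out <- do.call(rbind, lapply(seq_len(nrow(classes)), function(i) {
    g <- classes$gene[i]
    rows <- variants$gene == g
    data.frame(gene = g, class = classes$class[i],
               n_samples_loh =
                 length(unique(variants$sample_id[rows & loh])),
               n_variants = sum(rows),
               n_homozygous = sum(rows & hom),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Rank-sum test on per-gene LOH counts, TSG versus oncogene
#'
#' Two-sided Wilcoxon rank-sum test comparing `n_samples_loh` between
#' TSGs and oncogenes (exact enumeration for small gene counts).
#' Omitted (`NA`) when either class has fewer than `min_group` genes.
#'
#' @param counts output of [tally_by_class()].
#' @param min_group minimum genes per class (default 2).
#' @return two-sided p-value, or `NA` when omitted.
#' @export
loh_ranksum <- function(counts, min_group = 2L) {
  x <- counts$n_samples_loh[counts$class == "TSG"]
  y <- counts$n_samples_loh[counts$class == "oncogene"]
  if (length(x) < min_group || length(y) < min_group) return(NA_real_)
  ranksum_p(x, y)
}

#' Fisher exact test on pooled homozygous/heterozygous counts
#'
#' Pools variants over all genes of each class and builds the 2x2 table
#' of class (TSG / oncogene) by zygosity (homozygous / heterozygous).
#' The two-sided Fisher exact p sums the probabilities of all tables
#' (at the observed margins) no more likely than the observed one; the
#' odds ratio is the conditional maximum-likelihood estimate.
#' `fold_difference` is the TSG homozygous fraction divided by the
#' oncogene homozygous fraction (NA when a class has no variants or the
#' oncogene fraction is zero gives `Inf`).
#'
#' @param counts output of [tally_by_class()], or any data.frame with
#'   `class`, `n_variants`, `n_homozygous` (e.g. pooled counts entered
#'   directly from a publication table).
#' @return list with `homozygosity_table` (2x2 matrix), `fisher_p`,
#'   `odds_ratio`, `fold_difference`.
#' @export
homozygosity_fisher <- function(counts) {
  stopifnot(all(c("class", "n_variants", "n_homozygous") %in%
                  names(counts)))
  if (any(counts$n_homozygous > counts$n_variants)) {
    stop("n_homozygous exceeds n_variants", call. = FALSE)
  }
  pool <- function(cl, col) sum(counts[[col]][counts$class == cl])
  n_t <- pool("TSG", "n_variants"); hom_t <- pool("TSG", "n_homozygous")
  n_o <- pool("oncogene", "n_variants")
  hom_o <- pool("oncogene", "n_homozygous")
  tab <- matrix(c(hom_t, n_t - hom_t, hom_o, n_o - hom_o), nrow = 2L,
                dimnames = list(zygosity = c("homozygous",
                                             "heterozygous"),
                                class = c("TSG", "oncogene")))
  if (n_t == 0L || n_o == 0L) {
    return(list(homozygosity_table = tab, fisher_p = NA_real_,
                odds_ratio = NA_real_, fold_difference = NA_real_))
  }
  ft <- fisher.test(tab)
  frac_t <- hom_t / n_t
  frac_o <- hom_o / n_o
  fold <- if (frac_o == 0) Inf else frac_t / frac_o
  list(homozygosity_table = tab,
       fisher_p = ft$p.value,
       odds_ratio = unname(ft$estimate),
       fold_difference = fold)
}

#' TSG-versus-oncogene zygosity enrichment analysis
#'
#' Runs [tally_by_class()], the per-gene LOH rank-sum test and the
#' pooled homozygosity Fisher test in one call.
#'
#' @inheritParams tally_by_class
#' @param min_group minimum genes per class for the rank-sum test.
#' @return object of class `zygosity_enrichment`: the per-gene counts
#'   plus `loh_p`, `homozygosity_table`, `fisher_p`, `odds_ratio`,
#'   `fold_difference`.
#' @export
zygosity_enrichment <- function(variants, classes, hom_vaf = 0.8,
                                min_group = 2L) {
  counts <- tally_by_class(variants, classes, hom_vaf)
  fis <- homozygosity_fisher(counts)
  structure(c(list(counts = counts,
                   loh_p = loh_ranksum(counts, min_group)),
              fis),
            class = "zygosity_enrichment")
}

#' @export
print.zygosity_enrichment <- function(x, ...) {
  cat("Zygosity enrichment, TSG vs oncogene\n")
  n_t <- sum(x$counts$class == "TSG")
  n_o <- sum(x$counts$class == "oncogene")
  cat(sprintf("  genes: %d TSG, %d oncogene\n", n_t, n_o))
  cat(sprintf("  per-gene LOH rank-sum p = %s\n",
              ifelse(is.na(x$loh_p), "omitted",
                     format(signif(x$loh_p, 3)))))
  cat("  pooled homozygous/heterozygous counts:\n")
  print(x$homozygosity_table)
  cat(sprintf("  Fisher exact p = %s, odds ratio = %s, fold = %s\n",
              format(signif(x$fisher_p, 3)),
              format(signif(x$odds_ratio, 3)),
              format(signif(x$fold_difference, 3))))
  invisible(x)
}
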