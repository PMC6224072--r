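# All-pathway screen at fixed selection thresholds, redundancy pruning
# of correlated mutation profiles, and the volcano summary table.

#' Screen a pathway collection at fixed selection thresholds
#'
#' Applies the VAF/MAF selection filters once, then assigns pathway
#' mutation status and computes the rank-sum association for every
#' pathway.  Optionally a per-(sample, gene) mutation-status override is
#' applied after filtering (e.g. to correct genotypes known to be
#' miscalled, such as mutations missed by short-read sequencing):
#' `mutated = FALSE` rows delete that sample's retained variants in the
#' gene, `mutated = TRUE` rows insert a status-defining marker variant.
#'
#' @param variants call-filtered variant table.
#' @param pathways list of [gene_set()] objects.
#' @param phenotypes phenotype table.
#' @param vaf_threshold,maf_threshold selection thresholds
#'   (`NULL` = filter off); defaults 0.8 and 0.01 select homozygous
#'   variants and rare SNPs.
#' @param min_group minimum group size for the rank-sum test.
#' @param override optional data.frame with columns `sample_id`, `gene`,
#'   `mutated` (logical).
#' @param prune prune correlated mutation profiles
#'   (see [prune_correlated()])?
#' @param corr_threshold Pearson correlation at or above which two
#'   profiles are redundant (default 0.75).
#' @param p_adjust `"none"` (default: raw p-values, mirroring the
#'   exploratory usage) or `"BH"` to add a Benjamini-Hochberg adjusted
#'   column `p_adjusted`.
#' @return data.frame of class `pathway_screen` with columns `pathway`,
#'   `n_mutated`, `p_value`, `delta_ic50`, `pruned`, `pruned_by`;
#'   attribute `"profiles"` holds the samples x pathways 0/1
#'   mutation-status matrix.
#' @export
screen_pathways <- function(variants, pathways, phenotypes,
                            vaf_threshold = 0.8, maf_threshold = 0.01,
                            min_group = 2L, override = NULL,
                            prune = TRUE, corr_threshold = 0.75,
                            p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(length(pathways) > 0L)
  phenotypes <- as_phenotype_table(phenotypes)
  sel <- maf_select(vaf_select(variants, vaf_threshold), maf_threshold)
  if (!is.null(override)) sel <- apply_status_override(sel, override)
  nms <- unname(vapply(pathways, `[[`, "", "name"))
  if (anyDuplicated(nms)) {
    stop("duplicate pathway names", call. = FALSE)
  }
  profiles <- matrix(0L, nrow = nrow(phenotypes), ncol = length(pathways),
                     dimnames = list(phenotypes$sample_id, nms))
  rows <- lapply(seq_along(pathways), function(i) {
    status <- assign_status(sel, pathways[[i]], phenotypes)
    profiles[, i] <<- as.integer(status$mutated)
    assoc <- ranksum_association(status, phenotypes, min_group)
    data.frame(pathway = nms[i],
               n_mutated = assoc$n_mutated,
               p_value = assoc$p_value,
               delta_ic50 = assoc$delta_ic50,
               omitted = assoc$omitted,
               pruned = FALSE, pruned_by = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (p_adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  }
  class(out) <- c("pathway_screen", "data.frame")
  attr(out, "profiles") <- profiles
  attr(out, "vaf_threshold") <- vaf_threshold
  attr(out, "maf_threshold") <- maf_threshold
  if (prune) out <- prune_correlated(out, profiles, corr_threshold)
  out
}

apply_status_override <- function(variants, override) {
  stopifnot(is.data.frame(override),
            all(c("sample_id", "gene", "mutated") %in% names(override)))
  variants <- as_variant_table(variants)
  off <- override[!override$mutated, , drop = FALSE]
  if (nrow(off) > 0L) {
    drop <- paste(variants$sample_id, variants$gene) %in%
      paste(off$sample_id, off$gene)
    variants <- variants[!drop, , drop = FALSE]
  }
  on <- override[override$mutated, , drop = FALSE]
  if (nrow(on) > 0L) {
    marker <- data.frame(sample_id = as.character(on$sample_id),
                         gene = as.character(on$gene),
                         chrom = "override", pos = 1L,
                         ref = "N", alt = "N", kind = "SNV",
                         depth = 1L, alt_reads = 1L, vaf = 1,
                         maf = NA_real_, consequence = "other",
                         score = NA_real_, loh = NA,
                         stringsAsFactors = FALSE)
    variants <- rbind(variants, marker)
  }
  rownames(variants) <- NULL
  variants
}

# Pearson correlation of two 0/1 profiles; constant profiles have no
# defined correlation and are treated as redundant only with an
# identical profile.
profile_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) {
    return(if (identical(as.integer(a), as.integer(b))) 1 else -Inf)
  }
  cor(a, b)
}

#' Prune pathways with redundant mutation profiles
#'
#' Pathways sharing genes produce near-identical 0/1 mutation profiles.
#' For every pair with Pearson correlation `>= corr_threshold` the row
#' with the weaker association (larger p) is marked `pruned`, recording
#' the stronger pathway in `pruned_by`.  Rows are processed greedily in
#' ascending-p order (omitted rows last, ties by pathway name), so every
#' survivor has the smallest p in its redundancy neighborhood and
#' `pruned_by` always names a survivor.  Pruned rows are flagged, never
#' dropped.
#'
#' @param rows a `pathway_screen` data.frame (or compatible).
#' @param profiles samples x pathways 0/1 matrix, columns aligned to
#'   `rows$pathway`.
#' @param corr_threshold correlation threshold (default 0.75); a value
#'   above 1 disables pruning.
#' @return `rows` with `pruned` / `pruned_by` filled in.
#' @export
prune_correlated <- function(rows, profiles, corr_threshold = 0.75) {
  stopifnot(is.matrix(profiles),
            ncol(profiles) == nrow(rows),
            identical(colnames(profiles), rows$pathway))
  n <- nrow(rows)
  rows$pruned <- FALSE
  rows$pruned_by <- NA_character_
  if (n < 2L) return(rows)
  ord <- order(is.na(rows$p_value), rows$p_value, rows$pathway)
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    if (rows$pruned[i]) next
    for (b in seq((a + 1L), n)) {
      j <- ord[b]
      if (rows$pruned[j]) next
      if (profile_cor(profiles[, i], profiles[, j]) >= corr_threshold) {
        rows$pruned[j] <- TRUE
        rows$pruned_by[j] <- rows$pathway[i]
      }
    }
  }
  rows
}

#' Volcano summary table of a pathway screen
#'
#' One row per pathway: effect size (`delta_ic50`, x-axis), significance
#' (`neg_log10_p`, y-axis), `n_mutated` (dot size) and the `pruned`
#' flag.  Sorted by p ascending (ties by pathway name; omitted rows
#' last, with a blank `neg_log10_p`).
#'
#' @param rows a `pathway_screen` data.frame.
#' @param path optional output TSV path (written with [write_results()]).
#' @return the summary data.frame, invisibly when `path` is given.
#' @export
volcano_table <- function(rows, path = NULL) {
  out <- data.frame(pathway = rows$pathway,
                    delta_ic50 = rows$delta_ic50,
                    neg_log10_p = -log10(rows$p_value),
                    n_mutated = rows$n_mutated,
                    pruned = rows$pruned,
                    stringsAsFactors = FALSE)
  out <- out[order(is.na(rows$p_value), rows$p_value, rows$pathway), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    write_results(out, path)
    return(invisible(out))
  }
  out
}

#' @export
print.pathway_screen <- function(x, n = 10L, ...) {
  cat("Pathway screen: ", nrow(x), " pathways (VAF >= ",
      format(attr(x, "vaf_threshold")), ", MAF <= ",
      format(attr(x, "maf_threshold")), "), ",
      sum(x$pruned), " pruned as redundant\n", sep = "")
  vt <- volcano_table(x)
  print.data.frame(head(vt, n), digits = 4)
  if (nrow(vt) > n) cat("... and ", nrow(vt) - n, " more rows\n", sep = "")
  invisible(x)
}

#' Volcano plot of a pathway screen
#'
#' Mean IC50 difference against -log10 p; dot area scales with the
#' number of mutated samples; pruned pathways are drawn hollow.
#'
#' @param x a `pathway_screen` object.
#' @param label_top label this many smallest-p pathways.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pathway_screen <- function(x, label_top = 3L, ...) {
  ok <- !is.na(x$p_value)
  d <- x[ok, , drop = FALSE]
  y <- -log10(d$p_value)
  cex <- 0.6 + 1.6 * sqrt(d$n_mutated / max(1L, max(d$n_mutated)))
  plot(d$delta_ic50, y, pch = ifelse(d$pruned, 1, 16), cex = cex,
       xlab = "difference in mean IC50 (mutated - non-mutated)",
       ylab = expression(-log[10] ~ italic(p)), ...)
  abline(h = -log10(0.05), lty = 2, col = "grey50")
  top <- order(d$p_value)[seq_len(min(label_top, nrow(d)))]
  text(d$delta_ic50[top], y[top], d$pathway[top], pos = 3, cex = 0.7)
  invisible(x)
}
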