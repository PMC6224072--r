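# Post-calling QC and the zygosity/rarity/deleteriousness selection
# filters.  All filters are pure row subsets that preserve input order;
# threshold comparisons are inclusive (>= for VAF and score, <= for MAF).

#' Variant filter specification
#'
#' Holds the post-calling QC thresholds and the optional selection
#' thresholds.  Call-level defaults: SNVs require total depth >= 10,
#' >= 4 variant reads and VAF >= 0.10; indels require >= 10 variant
#' reads with no VAF restriction (the depth requirement still applies);
#' SNVs within `adjacency_window` bases (default 1) of a retained indel
#' in the same sample are discarded as alignment artifacts.
#'
#' @param min_depth minimum total read depth at the site.
#' @param min_alt_reads_snv minimum variant-supporting reads for SNVs.
#' @param min_vaf_call minimum VAF for an SNV call.
#' @param min_alt_reads_indel minimum variant-supporting reads for
#'   insertions/deletions (no VAF condition).
#' @param adjacency_window distance in bases within which an SNV next to
#'   a retained indel is removed.
#' @param consequence_whitelist consequence classes kept by
#'   [restrict_consequences()].
#' @param vaf_threshold,maf_threshold,score_threshold optional selection
#'   thresholds (`NULL` = filter off) applied by [select_variants()].
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(min_depth = 10L,
                        min_alt_reads_snv = 4L,
                        min_vaf_call = 0.10,
                        min_alt_reads_indel = 10L,
                        adjacency_window = 1L,
                        consequence_whitelist = DAMAGING_CONSEQUENCES,
                        vaf_threshold = NULL,
                        maf_threshold = NULL,
                        score_threshold = NULL) {
  stopifnot(min_depth >= 0, min_alt_reads_snv >= 0,
            min_vaf_call >= 0, min_vaf_call <= 1,
            min_alt_reads_indel >= 0, adjacency_window >= 0,
            length(consequence_whitelist) > 0L)
  unknown <- setdiff(consequence_whitelist, CONSEQUENCE_CLASSES)
  if (length(unknown) > 0L) {
    stop("unknown consequence class(es) in whitelist: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(min_depth = as.integer(min_depth),
                 min_alt_reads_snv = as.integer(min_alt_reads_snv),
                 min_vaf_call = as.numeric(min_vaf_call),
                 min_alt_reads_indel = as.integer(min_alt_reads_indel),
                 adjacency_window = as.integer(adjacency_window),
                 consequence_whitelist = consequence_whitelist,
                 vaf_threshold = vaf_threshold,
                 maf_threshold = maf_threshold,
                 score_threshold = score_threshold),
            class = "filter_spec")
}

#' Apply call-level quality filters
#'
#' Retains SNVs with `depth >= min_depth`, `alt_reads >=
#' min_alt_reads_snv` and `vaf >= min_vaf_call`; retains indels with
#' `depth >= min_depth` and `alt_reads >= min_alt_reads_indel`
#' regardless of VAF.  SNVs lying within `adjacency_window` bases of a
#' *retained* indel in the same sample are then removed.  Row order is
#' preserved.
#'
#' @param variants variant table.
#' @param spec a [filter_spec()].
#' @return filtered variant table.
#' @export
apply_call_filters <- function(variants, spec = filter_spec()) {
  variants <- as_variant_table(variants)
  is_snv <- variants$kind == "SNV"
  keep <- ifelse(is_snv,
                 variants$depth >= spec$min_depth &
                   variants$alt_reads >= spec$min_alt_reads_snv &
                   variants$vaf >= spec$min_vaf_call,
                 variants$depth >= spec$min_depth &
                   variants$alt_reads >= spec$min_alt_reads_indel)
  out <- variants[keep, , drop = FALSE]
  # adjacency: SNVs near a retained indel (same sample, same chromosome)
  indels <- out[out$kind != "SNV", , drop = FALSE]
  if (nrow(indels) > 0L) {
    snv_idx <- which(out$kind == "SNV")
    drop <- vapply(snv_idx, function(i) {
      near <- indels$sample_id == out$sample_id[i] &
        indels$chrom == out$chrom[i] &
        abs(indels$pos - out$pos[i]) <= spec$adjacency_window
      any(near)
    }, NA)
    if (any(drop)) out <- out[-snv_idx[drop], , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Remove recurrent artifacts seen in a panel of normal samples
#'
#' A variant (keyed by `chrom:pos:ref:alt`) observed in at least
#' `n_required` of the listed normal samples is treated as a technical
#' artifact and removed from every other sample.  The normals' own
#' records are dropped from the output.  By default a variant must occur
#' in *all* listed normals to be removed.
#'
#' @param variants variant table containing both study and normal samples.
#' @param normal_samples character vector of normal sample ids.
#' @param n_required number of normals a variant must appear in to be
#'   removed (default: all of them).
#' @return variant table without normal samples and without artifacts.
#' @export
remove_panel_of_normals <- function(variants, normal_samples,
                                    n_required = length(normal_samples)) {
  variants <- as_variant_table(variants)
  if (length(normal_samples) == 0L) {
    warning("no normal samples supplied; panel-of-normals filter is a no-op")
    return(variants)
  }
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
               sep = ":")
  is_normal <- variants$sample_id %in% normal_samples
  norm_keys <- tapply(variants$sample_id[is_normal], key[is_normal],
                      function(s) length(unique(s)))
  artifact_keys <- names(norm_keys)[norm_keys >= n_required]
  out <- variants[!is_normal & !(key %in% artifact_keys), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict to (potentially) protein-damaging consequence classes
#'
#' Keeps only records whose `consequence` lies in the whitelist; the
#' default keeps all non-synonymous exonic classes plus essential splice
#' site variants and drops synonymous/other.
#'
#' @param variants variant table.
#' @param whitelist consequence classes to keep.
#' @return filtered variant table.
#' @export
restrict_consequences <- function(variants,
                                  whitelist = DAMAGING_CONSEQUENCES) {
  variants <- as_variant_table(variants)
  unknown <- setdiff(whitelist, CONSEQUENCE_CLASSES)
  if (length(unknown) > 0L) {
    stop("unknown consequence class(es): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- variants[variants$consequence %in% whitelist, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select variants by allele zygosity (VAF threshold)
#'
#' Retains records with `vaf >= threshold` (inclusive).  High VAF is a
#' proxy for homozygosity in pure diploid samples: heterozygous variants
#' cluster near 0.5 and homozygous variants near 1.0.
#'
#' @param variants variant table.
#' @param threshold VAF threshold in \[0, 1\]; `NULL` disables the filter.
#' @return filtered variant table.
#' @export
vaf_select <- function(variants, threshold) {
  variants <- as_variant_table(variants)
  if (is.null(threshold) || is.na(threshold)) return(variants)
  stopifnot(threshold >= 0, threshold <= 1)
  out <- variants[variants$vaf >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select variants by population rarity (MAF threshold)
#'
#' Variants without a population MAF annotation (non-SNPs) are always
#' retained.  SNPs are retained iff `maf <= threshold` (inclusive).
#' `threshold = NULL` (or `NA`) retains everything; `threshold = 0`
#' retains exactly the non-SNPs, i.e. removes every variant present in
#' the reference population panel.
#'
#' @param variants variant table.
#' @param threshold MAF threshold in \[0, 0.5\], or `NULL`/`NA` for no
#'   filter.
#' @return filtered variant table.
#' @export
maf_select <- function(variants, threshold) {
  variants <- as_variant_table(variants)
  if (is.null(threshold) || is.na(threshold)) return(variants)
  stopifnot(threshold >= 0, threshold <= 0.5)
  keep <- is.na(variants$maf) | variants$maf <= threshold
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select variants by a generic deleteriousness score
#'
#' Retains records with `score >= threshold`.  Every record must carry a
#' score; a missing score is an error (unlike MAF, absence has no
#' domain meaning here).
#'
#' @param variants variant table.
#' @param threshold score threshold; `NULL` disables the filter.
#' @return filtered variant table.
#' @export
score_select <- function(variants, threshold) {
  variants <- as_variant_table(variants)
  if (is.null(threshold) || is.na(threshold)) return(variants)
  if (anyNA(variants$score)) {
    stop("score_select: record(s) without a score at row(s) ",
         paste(which(is.na(variants$score)), collapse = ", "),
         call. = FALSE)
  }
  out <- variants[variants$score >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the selection filters of a [filter_spec()] in one call
#'
#' Convenience wrapper: [vaf_select()], then [maf_select()], then
#' [score_select()] (the filters act on disjoint fields, so order does
#' not affect the result).
#'
#' @param variants variant table.
#' @param spec a [filter_spec()]; only the `*_threshold` fields are used.
#' @return filtered variant table.
#' @export
select_variants <- function(variants, spec = filter_spec()) {
  out <- vaf_select(variants, spec$vaf_threshold)
  out <- maf_select(out, spec$maf_threshold)
  if (!is.null(spec$score_threshold)) {
    out <- score_select(out, spec$score_threshold)
  }
  out
}
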