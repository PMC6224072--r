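# Pathway mutation status and its association with the drug-sensitivity
# endpoint: Wilcoxon rank-sum test (exact enumeration for small groups),
# positive predictive value against the top-k most sensitive samples,
# threshold sweeps, and the two controls (length-matched random gene
# sets, nearest genes).

#' Assign per-sample pathway mutation status
#'
#' A sample is "pathway mutated" iff at least one of the (already
#' filtered) variants lies in a gene of the set; samples with none are
#' "non-mutated".
#'
#' @param variants filtered variant table.
#' @param gene_set a [gene_set()].
#' @param phenotypes phenotype table defining the sample universe.
#' @return data.frame with columns `sample_id`, `mutated`, `n_support`;
#'   attribute `"supporting"` maps each mutated sample to the row
#'   indices of its supporting variants in `variants`.
#' @export
assign_status <- function(variants, gene_set, phenotypes) {
  variants <- as_variant_table(variants)
  phenotypes <- as_phenotype_table(phenotypes)
  samples <- phenotypes$sample_id
  unknown <- setdiff(unique(variants$sample_id), samples)
  if (length(unknown) > 0L) {
    stop("variant(s) in sample(s) absent from the phenotype table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  hit <- which(variants$gene %in% gene_set$genes)
  support <- split(hit, factor(variants$sample_id[hit], levels = samples))
  n_support <- vapply(support, length, 1L)
  out <- data.frame(sample_id = samples,
                    mutated = n_support > 0L,
                    n_support = n_support,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "supporting") <- support[n_support > 0L]
  out
}

# Two-sided rank-sum p-value.  Exact permutation enumeration (mid-ranks,
# so ties are handled) when both groups have <= exact_max observations;
# otherwise the tie-corrected normal approximation.  With mid-ranks the
# null mean of the rank sum is n1 * (N + 1) / 2 regardless of ties, so
# "two-sided" is the probability of a rank sum at least as far from that
# mean as observed.
ranksum_p <- function(x, y, exact_max = 10L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) return(NA_real_)
  if (n1 <= exact_max && n2 <= exact_max) {
    N <- n1 + n2
    r <- rank(c(x, y))
    W <- sum(r[seq_len(n1)])
    E <- n1 * (N + 1) / 2
    idx <- combn(N, n1)
    sums <- colSums(matrix(r[idx], nrow = n1))
    return(mean(abs(sums - E) >= abs(W - E) - 1e-9))
  }
  suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
}

#' Rank-sum association between mutation status and IC50
#'
#' Two-sided Wilcoxon rank-sum test comparing the IC50 values of
#' mutated and non-mutated samples.  Exact permutation enumeration is
#' used when both groups have at most ten samples, a tie-corrected
#' normal approximation otherwise.  The test is omitted (`p_value = NA`)
#' when either group has fewer than `min_group` samples; the mean IC50
#' difference is still reported whenever both groups are non-empty.
#'
#' @param status output of [assign_status()].
#' @param phenotypes phenotype table.
#' @param min_group minimum per-group size for the test (default 2).
#' @return list with `p_value`, `delta_ic50` (mean mutated minus mean
#'   non-mutated), `n_mutated`, `n_nonmutated`, `omitted`.
#' @export
ranksum_association <- function(status, phenotypes, min_group = 2L) {
  phenotypes <- as_phenotype_table(phenotypes)
  ic <- setNames(phenotypes$ic50, phenotypes$sample_id)
  x <- ic[status$sample_id[status$mutated]]      # mutated
  y <- ic[status$sample_id[!status$mutated]]     # non-mutated
  delta <- if (length(x) > 0L && length(y) > 0L) mean(x) - mean(y)
           else NA_real_
  omitted <- length(x) < min_group || length(y) < min_group
  p <- if (omitted) NA_real_ else ranksum_p(x, y)
  list(p_value = p, delta_ic50 = delta,
       n_mutated = length(x), n_nonmutated = length(y),
       omitted = omitted)
}

#' Positive predictive value against the most drug-sensitive samples
#'
#' The PPV is the fraction of pathway-mutated samples found among the
#' `top_k` most sensitive samples (lowest IC50):
#' `|mutated & top_k| / n_mutated`.  Under mutation labels independent
#' of the IC50 ranking its expectation is `top_k / n_samples` whatever
#' the number of mutated samples.  `NA` when no sample is mutated.
#' Ties at the top-k boundary are broken by a stable sort on
#' `sample_id` (deterministic) and reported via a message.
#'
#' @param status output of [assign_status()].
#' @param phenotypes phenotype table.
#' @param top_k number of most-sensitive samples (default 10).
#' @param denominator `"mutated"` (default; fraction of mutated samples
#'   that are in the top k) or `"top_k"` (alternative reading: fraction
#'   of the top k that are mutated).
#' @return a single numeric PPV, or `NA`.
#' @export
ppv <- function(status, phenotypes, top_k = 10L,
                denominator = c("mutated", "top_k")) {
  denominator <- match.arg(denominator)
  phenotypes <- as_phenotype_table(phenotypes)
  if (top_k > nrow(phenotypes)) {
    stop("top_k exceeds the number of samples", call. = FALSE)
  }
  ord <- order(phenotypes$ic50, phenotypes$sample_id)
  sorted_ic <- phenotypes$ic50[ord]
  if (top_k < nrow(phenotypes) &&
      isTRUE(sorted_ic[top_k] == sorted_ic[top_k + 1L])) {
    message("ppv: IC50 tie at the top-", top_k,
            " boundary broken by sample_id order")
  }
  top <- phenotypes$sample_id[ord][seq_len(top_k)]
  mutated <- status$sample_id[status$mutated]
  if (length(mutated) == 0L) return(NA_real_)
  hits <- length(intersect(top, mutated))
  if (denominator == "mutated") hits / length(mutated) else hits / top_k
}

#' Associate one gene set with the IC50 endpoint at fixed thresholds
#'
#' Convenience wrapper: applies the optional VAF/MAF selection filters,
#' assigns mutation status, and computes the rank-sum association and
#' PPV.
#'
#' @param variants variant table (already call-filtered).
#' @param gene_set a [gene_set()].
#' @param phenotypes phenotype table.
#' @param vaf_threshold,maf_threshold selection thresholds
#'   (`NULL` = off).
#' @param top_k PPV top-k (default 10).
#' @param min_group minimum group size (default 2).
#' @return object of class `pathway_assoc`.
#' @export
pathway_association <- function(variants, gene_set, phenotypes,
                                vaf_threshold = NULL,
                                maf_threshold = NULL,
                                top_k = 10L, min_group = 2L) {
  sel <- maf_select(vaf_select(variants, vaf_threshold), maf_threshold)
  status <- assign_status(sel, gene_set, phenotypes)
  assoc <- ranksum_association(status, phenotypes, min_group)
  res <- c(list(gene_set_name = gene_set$name,
                vaf_threshold = if (is.null(vaf_threshold)) NA_real_
                                else vaf_threshold,
                maf_threshold = if (is.null(maf_threshold)) NA_real_
                                else maf_threshold,
                ppv = ppv(status, phenotypes, top_k),
                status = status),
           assoc)
  structure(res, class = "pathway_assoc")
}

#' @export
print.pathway_assoc <- function(x, ...) {
  cat("Pathway association: ", x$gene_set_name, "\n", sep = "")
  cat(sprintf("  thresholds: VAF >= %s, MAF <= %s\n",
              ifelse(is.na(x$vaf_threshold), "(off)",
                     format(x$vaf_threshold)),
              ifelse(is.na(x$maf_threshold), "(off)",
                     format(x$maf_threshold))))
  cat(sprintf("  mutated %d vs non-mutated %d samples\n",
              x$n_mutated, x$n_nonmutated))
  if (x$omitted) {
    cat("  rank-sum test omitted (group smaller than minimum)\n")
  } else {
    cat(sprintf("  rank-sum p = %.4g, mean IC50 difference = %.4g\n",
                x$p_value, x$delta_ic50))
  }
  cat(sprintf("  PPV (mutated among most sensitive) = %s\n",
              ifelse(is.na(x$ppv), "NA", format(round(x$ppv, 3)))))
  invisible(x)
}

#' Sweep selection thresholds and associate at each grid point
#'
#' Re-runs the gene-set association across a grid of VAF and/or MAF (or
#' score) thresholds.  `axis = "vaf"` sweeps `vaf_grid` with no MAF
#' filter, `axis = "maf"` sweeps `maf_grid` with no VAF filter,
#' `axis = "both"` crosses the two grids (families of curves), and
#' `axis = "score"` sweeps `score_grid`.
#'
#' @param variants call-filtered variant table.
#' @param gene_set a [gene_set()].
#' @param phenotypes phenotype table.
#' @param config a [run_config()].
#' @param axis one of `"vaf"`, `"maf"`, `"both"`, `"score"`.
#' @return data.frame of class `assoc_sweep`: one row per grid point
#'   with `gene_set_name`, thresholds, `n_mutated`, `p_value`, `ppv`,
#'   `delta_ic50`, `omitted`, ordered by threshold.
#' @export
sweep_association <- function(variants, gene_set, phenotypes,
                              config = run_config(),
                              axis = c("vaf", "maf", "both", "score")) {
  axis <- match.arg(axis)
  variants <- as_variant_table(variants)
  grid <- switch(axis,
    vaf = data.frame(vaf = config$vaf_grid, maf = NA_real_,
                     score = NA_real_),
    maf = data.frame(vaf = NA_real_, maf = config$maf_grid,
                     score = NA_real_),
    both = {
      g <- expand.grid(vaf = config$vaf_grid, maf = config$maf_grid)
      data.frame(vaf = g$vaf, maf = g$maf, score = NA_real_)
    },
    score = {
      if (is.null(config$score_grid)) {
        stop("axis = 'score' requires score_grid in the config",
             call. = FALSE)
      }
      data.frame(vaf = NA_real_, maf = NA_real_,
                 score = config$score_grid)
    })
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- vaf_select(variants, grid$vaf[i])
    sel <- maf_select(sel, grid$maf[i])
    if (!is.na(grid$score[i])) sel <- score_select(sel, grid$score[i])
    status <- assign_status(sel, gene_set, phenotypes)
    assoc <- ranksum_association(status, phenotypes, config$min_group)
    data.frame(gene_set_name = gene_set$name,
               vaf_threshold = grid$vaf[i],
               maf_threshold = grid$maf[i],
               score_threshold = grid$score[i],
               n_retained = nrow(sel),
               n_mutated = assoc$n_mutated,
               p_value = assoc$p_value,
               ppv = ppv(status, phenotypes, config$top_k),
               delta_ic50 = assoc$delta_ic50,
               omitted = assoc$omitted,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("assoc_sweep", "data.frame")
  attr(out, "axis") <- axis
  out
}

#' Draw random gene sets length-matched to a target
#'
#' Samples `n` gene sets whose cumulative target length lies within
#' `target_length * (1 +/- tolerance)`.  Genes are drawn without
#' replacement within a set; genes listed in `exclude` (typically the
#' tested pathway's own members) never enter a set.  Used as the
#' "similar sized gene sets" null for the PPV and rank-sum statistics.
#'
#' @param annotation gene annotation table (lengths).
#' @param target_length target cumulative length in bases.
#' @param n number of sets.
#' @param tolerance relative length tolerance (default 0.10).
#' @param exclude gene symbols never to include.
#' @param seed optional integer seed.
#' @param max_retries attempts per set before giving up.
#' @return list of [gene_set()] objects named `random_set_00001`, ...
#' @export
random_gene_sets <- function(annotation, target_length, n,
                             tolerance = 0.10, exclude = character(),
                             seed = NULL, max_retries = 1000L) {
  annotation <- as_gene_annotation(annotation)
  if (!is.null(seed)) set.seed(seed)
  pool <- annotation[!(annotation$gene %in% exclude), , drop = FALSE]
  lens <- pool$length
  m <- nrow(pool)
  if (m == 0L) stop("no candidate genes after exclusion", call. = FALSE)
  lo <- target_length * (1 - tolerance)
  hi <- target_length * (1 + tolerance)
  out <- vector("list", n)
  for (b in seq_len(n)) {
    ok <- FALSE
    for (r in seq_len(max_retries)) {
      perm <- sample.int(m)
      cs <- cumsum(lens[perm])
      i <- which(cs >= lo & cs <= hi)
      if (length(i) > 0L) {
        take <- perm[seq_len(i[1L])]
        out[[b]] <- gene_set(sprintf("random_set_%05d", b),
                             pool$gene[take], cs[i[1L]])
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not reach target length ", target_length,
           " within tolerance ", tolerance, " after ", max_retries,
           " attempts", call. = FALSE)
    }
  }
  setNames(out, vapply(out, `[[`, "", "name"))
}

#' Nearest-gene control set
#'
#' For each member of `gene_set`, finds the nearest non-member gene on
#' the same chromosome by `order_index` (ties broken toward the lower
#' index).  Two members may share a neighbor, so the control can be
#' smaller than the pathway.  Variants in these immediate genomic
#' neighbors should carry no pathway signal; the control guards against
#' positional artifacts.
#'
#' @param annotation gene annotation table with `order_index`.
#' @param gene_set a [gene_set()].
#' @return a [gene_set()] named `<name>_nearest`.
#' @export
nearest_gene_control <- function(annotation, gene_set) {
  annotation <- as_gene_annotation(annotation)
  members <- gene_set$genes
  missing <- setdiff(members, annotation$gene)
  if (length(missing) > 0L) {
    stop("gene(s) absent from annotation: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  neighbors <- vapply(members, function(g) {
    row <- annotation[annotation$gene == g, , drop = FALSE][1L, ]
    cand <- annotation[annotation$chrom == row$chrom &
                         !(annotation$gene %in% members), , drop = FALSE]
    if (nrow(cand) == 0L) return(NA_character_)
    d <- abs(cand$order_index - row$order_index)
    cand <- cand[order(d, cand$order_index), , drop = FALSE]
    cand$gene[1L]
  }, "")
  neighbors <- unique(neighbors[!is.na(neighbors)])
  if (length(neighbors) == 0L) {
    stop("no non-member neighbors found for set '", gene_set$name, "'",
         call. = FALSE)
  }
  len <- sum(annotation$length[annotation$gene %in% neighbors])
  gene_set(paste0(gene_set$name, "_nearest"), neighbors, len)
}
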