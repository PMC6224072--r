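# Domain containers: variant tables, phenotypes, gene sets, annotation,
# run configuration.  Variant tables are plain data.frames with a fixed
# column vocabulary so that every filter is an ordinary row subset.

#' Column names of a variant table
#'
#' A variant table is a `data.frame` with one row per called variant in
#' one sample.  Mandatory columns: `sample_id`, `gene`, `chrom`, `pos`
#' (1-based), `ref`, `alt`, `kind` (`SNV`/`INS`/`DEL`), `depth`,
#' `alt_reads`, `consequence`.  `vaf` is computed as
#' `alt_reads / depth` when missing.  Optional columns `maf` (population
#' minor allele frequency; `NA` means the variant is not a SNP), `score`
#' (generic deleteriousness score) and `loh` (logical loss-of-
#' heterozygosity flag) are filled with `NA` when absent.
#' @name variant-table
NULL

VARIANT_COLUMNS <- c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                     "kind", "depth", "alt_reads", "vaf", "maf",
                     "consequence", "score", "loh")

MANDATORY_VARIANT_COLUMNS <- setdiff(VARIANT_COLUMNS,
                                     c("vaf", "maf", "score", "loh"))

VARIANT_KINDS <- c("SNV", "INS", "DEL")

CONSEQUENCE_CLASSES <- c("nonsynonymous", "stopgain", "stoploss",
                         "frameshift", "nonframeshift_indel",
                         "splice_essential", "synonymous", "other")

#' Consequence classes treated as potentially protein-damaging
#'
#' The default whitelist used by [restrict_consequences()]: all
#' non-synonymous exonic classes plus essential splice-site variants.
#' @export
DAMAGING_CONSEQUENCES <- c("nonsynonymous", "stopgain", "stoploss",
                           "frameshift", "nonframeshift_indel",
                           "splice_essential")

#' Validate and canonicalize a variant table
#'
#' Checks the invariants of a variant table (see [variant-table]):
#' mandatory columns present, `alt_reads <= depth`, `depth > 0`,
#' `vaf` in \[0, 1\], `maf` in \[0, 0.5\] or `NA`, `pos >= 1`, known
#' `kind` and `consequence` labels.  `vaf` is computed from read counts
#' when the column is missing; optional columns are filled with `NA`.
#' Offending rows are reported by row number in a single error.
#'
#' @param x data.frame of variants.
#' @return the canonicalized data.frame with columns in standard order.
#' @export
as_variant_table <- function(x) {
  stopifnot(is.data.frame(x))
  # row subsets of an already-validated table keep the marker class and
  # cannot break row-level invariants: skip re-validation
  if (inherits(x, "variant_tbl") &&
      identical(names(x), VARIANT_COLUMNS)) {
    return(x)
  }
  missing_cols <- setdiff(MANDATORY_VARIANT_COLUMNS, names(x))
  if (length(missing_cols) > 0L) {
    stop("variant table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in c("sample_id", "gene", "chrom", "ref", "alt", "kind",
                "consequence")) {
    x[[col]] <- as.character(x[[col]])
  }
  x$pos <- as.integer(x$pos)
  x$depth <- as.integer(x$depth)
  x$alt_reads <- as.integer(x$alt_reads)
  if (!"vaf" %in% names(x) || all(is.na(x$vaf))) {
    x$vaf <- ifelse(x$depth > 0, x$alt_reads / x$depth, NA_real_)
  }
  x$vaf <- as.numeric(x$vaf)
  if (!"maf" %in% names(x)) x$maf <- NA_real_
  x$maf <- as.numeric(x$maf)
  if (!"score" %in% names(x)) x$score <- NA_real_
  x$score <- as.numeric(x$score)
  if (!"loh" %in% names(x)) x$loh <- NA
  x$loh <- as.logical(x$loh)

  bad <- function(cond) which(!is.na(cond) & cond)
  problems <- list(
    "depth = 0"            = which(x$depth == 0L),
    "alt_reads > depth"    = bad(x$alt_reads > x$depth),
    "vaf outside [0,1]"    = bad(x$vaf < 0 | x$vaf > 1),
    "maf outside [0,0.5]"  = bad(x$maf < 0 | x$maf > 0.5),
    "pos < 1"              = bad(x$pos < 1L),
    "unknown kind"         = which(!x$kind %in% VARIANT_KINDS),
    "unknown consequence"  = which(!x$consequence %in% CONSEQUENCE_CLASSES)
  )
  problems <- problems[vapply(problems, length, 1L) > 0L]
  if (length(problems) > 0L) {
    msg <- vapply(names(problems), function(nm) {
      rows <- problems[[nm]]
      extra <- if (nm == "unknown consequence") {
        paste0(" [", paste(unique(x$consequence[rows]), collapse = ", "), "]")
      } else if (nm == "unknown kind") {
        paste0(" [", paste(unique(x$kind[rows]), collapse = ", "), "]")
      } else ""
      paste0(nm, extra, " at row(s) ", paste(rows, collapse = ", "))
    }, "")
    stop("invalid variant record(s): ", paste(msg, collapse = "; "),
         call. = FALSE)
  }
  rownames(x) <- NULL
  x <- x[, VARIANT_COLUMNS]
  class(x) <- c("variant_tbl", "data.frame")
  x
}

#' Construct a gene set
#'
#' A named, duplicate-free collection of gene symbols, optionally with the
#' cumulative target length (bases) of its members, used for
#' length-matched null sets.
#'
#' @param name set identifier.
#' @param genes character vector of gene symbols (non-empty; duplicates
#'   are removed).
#' @param cumulative_length total targeted bases of the member genes, or
#'   `NA` when unknown.
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(name, genes, cumulative_length = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- unique(as.character(genes))
  if (length(genes) < 1L) {
    stop("gene set '", name, "' has no genes", call. = FALSE)
  }
  structure(list(name = name, genes = genes,
                 cumulative_length = as.numeric(cumulative_length)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("Gene set '", x$name, "': ", length(x$genes), " genes",
      if (!is.na(x$cumulative_length))
        paste0(", ", format(x$cumulative_length, big.mark = ","),
               " targeted bases"),
      "\n", sep = "")
  cat("  ", paste(head(x$genes, 8L), collapse = ", "),
      if (length(x$genes) > 8L) ", ...", "\n", sep = "")
  invisible(x)
}

#' Validate a phenotype table
#'
#' One row per sample: `sample_id` and `ic50` (drug concentration at 50%
#' survival; positive, arbitrary concentration units).  Sample ids must
#' be unique.
#'
#' @param x data.frame with columns `sample_id`, `ic50`.
#' @return validated data.frame.
#' @export
as_phenotype_table <- function(x) {
  stopifnot(is.data.frame(x))
  if (!all(c("sample_id", "ic50") %in% names(x))) {
    stop("phenotype table needs columns sample_id, ic50", call. = FALSE)
  }
  x <- data.frame(sample_id = as.character(x$sample_id),
                  ic50 = as.numeric(x$ic50),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(x$sample_id)) {
    stop("duplicate sample_id in phenotype table: ",
         paste(unique(x$sample_id[duplicated(x$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x$ic50) | x$ic50 <= 0)) {
    stop("ic50 must be positive and finite", call. = FALSE)
  }
  x
}

#' Validate a gene annotation table
#'
#' Columns: `gene`, `length` (positive targeted bases), `chrom`,
#' `order_index` (integer rank of the gene along its chromosome; unique
#' per chromosome; used for nearest-gene lookups) and optional `class`
#' (`TSG`, `oncogene` or `other`).
#'
#' @param x data.frame.
#' @return validated data.frame.
#' @export
as_gene_annotation <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("gene", "length", "chrom", "order_index")
  if (!all(need %in% names(x))) {
    stop("gene annotation needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(gene = as.character(x$gene),
                    length = as.numeric(x$length),
                    chrom = as.character(x$chrom),
                    order_index = as.integer(x$order_index),
                    class = if ("class" %in% names(x))
                      as.character(x$class) else NA_character_,
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$length) | out$length <= 0)) {
    stop("gene lengths must be positive", call. = FALSE)
  }
  if (anyDuplicated(out$gene)) {
    stop("duplicate gene symbols in annotation", call. = FALSE)
  }
  dup <- unsplit(lapply(split(out$order_index, out$chrom), duplicated),
                 out$chrom)
  if (any(dup)) {
    stop("order_index must be unique within each chromosome",
         call. = FALSE)
  }
  out
}

#' Analysis run configuration
#'
#' Holds the threshold grids and tuning constants shared by the sweep and
#' screen stages.  Defaults mirror a 29-sample cell-line panel analysis:
#' `top_k = 10` most sensitive samples for the PPV, 10,000 length-matched
#' random sets within +/-10% of the target length, mutation-profile
#' pruning at Pearson correlation 0.75, and statistics omitted when a
#' group has fewer than two samples.
#'
#' @param vaf_grid increasing VAF thresholds in \[0, 1\].
#' @param maf_grid increasing MAF thresholds in \[0, 0.5\]; a trailing
#'   `NA` is the "no MAF filter" sentinel.
#' @param score_grid optional increasing deleteriousness-score thresholds.
#' @param top_k number of most-sensitive samples defining the PPV numerator.
#' @param n_null_sets number of random length-matched gene sets.
#' @param length_tolerance relative tolerance on cumulative set length.
#' @param corr_threshold Pearson correlation above which mutation
#'   profiles are considered redundant.
#' @param min_group minimum per-group sample count for a rank-sum test.
#' @param seed integer seed for reproducible random sets.
#' @return an object of class `run_config`.
#' @export
run_config <- function(vaf_grid = seq(0, 0.9, by = 0.1),
                       maf_grid = c(0, 0.001, 0.005, 0.01, 0.05, 0.1,
                                    0.2, 0.5, NA),
                       score_grid = NULL,
                       top_k = 10L,
                       n_null_sets = 10000L,
                       length_tolerance = 0.10,
                       corr_threshold = 0.75,
                       min_group = 2L,
                       seed = 1L) {
  check_grid <- function(g, lo, hi, what, na_ok = FALSE) {
    if (is.null(g)) return(NULL)
    g <- as.numeric(g)
    vals <- g[!is.na(g)]
    if (any(is.na(g)) && (!na_ok || any(is.na(g[-length(g)])))) {
      stop(what, ": NA sentinel only allowed as the last element",
           call. = FALSE)
    }
    if (any(vals < lo | vals > hi)) {
      stop(what, " must lie in [", lo, ", ", hi, "]", call. = FALSE)
    }
    if (length(vals) > 1L && any(diff(vals) <= 0)) {
      stop(what, " must be strictly increasing", call. = FALSE)
    }
    g
  }
  cfg <- list(
    vaf_grid = check_grid(vaf_grid, 0, 1, "vaf_grid"),
    maf_grid = check_grid(maf_grid, 0, 0.5, "maf_grid", na_ok = TRUE),
    score_grid = if (is.null(score_grid)) NULL else as.numeric(score_grid),
    top_k = as.integer(top_k),
    n_null_sets = as.integer(n_null_sets),
    length_tolerance = as.numeric(length_tolerance),
    corr_threshold = as.numeric(corr_threshold),
    min_group = as.integer(min_group),
    seed = as.integer(seed)
  )
  stopifnot(cfg$top_k >= 1L, cfg$n_null_sets >= 1L,
            cfg$length_tolerance >= 0, cfg$min_group >= 1L)
  structure(cfg, class = "run_config")
}
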