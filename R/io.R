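# Readers and writers for the interchange formats: variant TSV/VCF,
# GMT gene sets, phenotype and annotation TSVs, YAML/JSON run configs,
# and result tables.  TSV is the canonical dialect; VCF is read-only.

fmt_num <- function(x) {
  # full-precision numeric formatting so write -> read round-trips exactly
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, "")
  out
}

write_tsv_exact <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- fmt_num(out[[col]])
  }
  tryCatch(
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA"),
    error = function(e) stop("cannot write '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}

#' Read a variant table from TSV or VCF
#'
#' TSV files must carry a header naming the variant-table columns (see
#' [variant-table]); `vaf` is computed as `alt_reads / depth` when the
#' column is absent.  VCF input (read via \pkg{vcfR}) expects per-sample
#' `AD` (allelic depths, `ref,alt`) and optionally `DP` and `LOH` FORMAT
#' fields, and site-level `GENE`, `CONSEQ`, `MAF`, `SCORE` INFO keys; a
#' record is emitted for every sample whose genotype carries the
#' alternate allele.
#'
#' @param path file path.
#' @param dialect `"tsv"` (canonical) or `"vcf"`.
#' @return a validated variant table (data.frame).
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "tsv") {
    hdr <- names(read.delim(path, nrows = 0L))
    char_cols <- intersect(c("sample_id", "gene", "chrom", "ref", "alt",
                             "kind", "consequence"), hdr)
    df <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = setNames(rep("character",
                                               length(char_cols)),
                                           char_cols))
    return(as_variant_table(df))
  }
  read_variant_vcf(path)
}

read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_site <- nrow(fix)
  info1 <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    if (is.null(val)) rep(NA_character_, n_site) else val
  }
  gene <- info1("GENE")
  conseq <- info1("CONSEQ")
  maf <- suppressWarnings(as.numeric(info1("MAF")))
  score <- suppressWarnings(as.numeric(info1("SCORE")))
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP",
                                          as.numeric = TRUE))
  loh <- tryCatch(vcfR::extract.gt(v, element = "LOH"),
                  error = function(e) NULL)
  samples <- colnames(gt)
  rows <- list()
  for (s in samples) {
    has_alt <- !is.na(gt[, s]) & grepl("1", gt[, s], fixed = TRUE)
    idx <- which(has_alt)
    if (length(idx) == 0L) next
    ad_s <- strsplit(ad[idx, s], ",", fixed = TRUE)
    ref_reads <- vapply(ad_s, function(a) as.integer(a[1]), 1L)
    alt_reads <- vapply(ad_s, function(a) as.integer(a[2]), 1L)
    depth <- if (!is.null(dp)) dp[idx, s] else ref_reads + alt_reads
    depth <- ifelse(is.na(depth), ref_reads + alt_reads, depth)
    ref <- fix[idx, "REF"]
    alt <- fix[idx, "ALT"]
    kind <- ifelse(nchar(ref) == nchar(alt) & nchar(ref) == 1L, "SNV",
                   ifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
    loh_s <- if (!is.null(loh)) {
      vals <- loh[idx, s]
      ifelse(is.na(vals) | vals == ".", NA, vals == "1")
    } else NA
    rows[[s]] <- data.frame(
      sample_id = s,
      gene = gene[idx],
      chrom = fix[idx, "CHROM"],
      pos = as.integer(fix[idx, "POS"]),
      ref = ref, alt = alt, kind = kind,
      depth = as.integer(depth), alt_reads = alt_reads,
      vaf = alt_reads / as.numeric(depth),
      maf = maf[idx],
      consequence = ifelse(is.na(conseq[idx]), "other", conseq[idx]),
      score = score[idx],
      loh = loh_s,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(as_variant_table(
      data.frame(sample_id = character(), gene = character(),
                 chrom = character(), pos = integer(), ref = character(),
                 alt = character(), kind = character(), depth = integer(),
                 alt_reads = integer(), consequence = character(),
                 stringsAsFactors = FALSE)))
  }
  as_variant_table(do.call(rbind, rows))
}

#' Write a variant table to TSV
#'
#' Canonical column order; full-precision numerics so that
#' `read_variant_table(write_variant_table(x))` reproduces `x` exactly.
#'
#' @param variants validated variant table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  variants <- as_variant_table(variants)
  write_tsv_exact(variants, path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...` (parsed with
#' \pkg{fgsea}).  Duplicate set names and member-less lines are errors.
#' When a gene annotation is supplied, each set's `cumulative_length` is
#' the summed target length of its annotated members.
#'
#' @param path GMT file path.
#' @param annotation optional gene annotation table
#'   (see [as_gene_annotation()]).
#' @return named list of [gene_set()] objects.
#' @export
read_gene_sets <- function(path, annotation = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
  raw <- raw[vapply(raw, length, 1L) > 0L]
  nms <- vapply(raw, `[`, "", 1L)
  if (anyDuplicated(nms)) {
    stop("duplicate gene set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "),
         call. = FALSE)
  }
  short <- vapply(raw, length, 1L) < 3L
  if (any(short)) {
    stop("gene set line(s) without genes: ",
         paste(nms[short], collapse = ", "), call. = FALSE)
  }
  sets <- fgsea::gmtPathways(path)
  out <- lapply(names(sets), function(nm) {
    genes <- unique(sets[[nm]])
    len <- NA_real_
    if (!is.null(annotation)) {
      annotation <- as_gene_annotation(annotation)
      len <- sum(annotation$length[annotation$gene %in% genes])
    }
    gene_set(nm, genes, len)
  })
  setNames(out, names(sets))
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @param description description field (second GMT column).
#' @return the path, invisibly.
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a phenotype table (sample_id, ic50) from TSV
#' @param path file path.
#' @return validated phenotype data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  as_phenotype_table(read.delim(path, stringsAsFactors = FALSE))
}

#' Write a phenotype table to TSV
#' @param phenotypes phenotype data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write_tsv_exact(as_phenotype_table(phenotypes), path)
}

#' Read a gene annotation table from TSV
#'
#' Columns `gene`, `length`, `chrom`, `order_index` and optional `class`.
#' @param path file path.
#' @return validated annotation data.frame.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  as_gene_annotation(read.delim(path, stringsAsFactors = FALSE,
                                colClasses = c(chrom = "character")))
}

#' Write a gene annotation table to TSV
#' @param annotation annotation data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  write_tsv_exact(as_gene_annotation(annotation), path)
}

#' Write a result table (association sweep, screen, enrichment counts)
#'
#' Deterministic column order (the data.frame's own order) and
#' full-precision numerics: `read_results(write_results(x))` reproduces
#' the values exactly.
#'
#' @param results data.frame of results; zero rows allowed
#'   (header-only file).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  write_tsv_exact(as.data.frame(results), path)
}

#' Read back a result table written by [write_results()]
#' @param path file path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read a run configuration from YAML or JSON
#'
#' Fields mirror [run_config()]; unknown fields are an error.  The YAML
#' value `.na` (or `null` as the final grid element) encodes the
#' "no MAF filter" sentinel.
#'
#' @param path YAML/JSON file.
#' @return a `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  raw <- lapply(raw, function(v) {
    if (is.list(v)) unlist(lapply(v, function(e)
      if (is.null(e)) NA_real_ else e)) else v
  })
  do.call(run_config, raw)
}
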