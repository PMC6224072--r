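# Fixture builders and independent statistical oracles used across the
# suite.  Oracles are deliberately written as naive enumerations so they
# share no code with the package implementations they check.

CONSEQ <- c("nonsynonymous", "stopgain", "stoploss", "frameshift",
            "nonframeshift_indel", "splice_essential", "synonymous",
            "other")

# one variant row with overridable fields
vrow <- function(sample_id = "S1", gene = "G1", chrom = "1", pos = 100L,
                 ref = "A", alt = "T", kind = "SNV", depth = 100L,
                 alt_reads = 50L, vaf = alt_reads / depth,
                 maf = NA_real_, consequence = "nonsynonymous",
                 score = NA_real_, loh = NA) {
  data.frame(sample_id = sample_id, gene = gene, chrom = chrom,
             pos = pos, ref = ref, alt = alt, kind = kind,
             depth = depth, alt_reads = alt_reads, vaf = vaf,
             maf = maf, consequence = consequence, score = score,
             loh = loh, stringsAsFactors = FALSE)
}

vtab <- function(...) as_variant_table(do.call(rbind, list(...)))

# randomized valid variant table for property tests
rand_variants <- function(n, n_samples = 4L, n_genes = 8L) {
  depth <- sample(10:200, n, replace = TRUE)
  alt_reads <- vapply(depth, function(d) sample.int(d, 1L), 1L)
  as_variant_table(data.frame(
    sample_id = sample(paste0("S", seq_len(n_samples)), n, TRUE),
    gene = sample(paste0("G", seq_len(n_genes)), n, TRUE),
    chrom = sample(c("1", "2", "X"), n, TRUE),
    pos = sample.int(100000L, n, TRUE),
    ref = sample(c("A", "C", "G", "T"), n, TRUE),
    alt = sample(c("A", "C", "G", "T"), n, TRUE),
    kind = sample(c("SNV", "INS", "DEL"), n, TRUE,
                  prob = c(0.8, 0.1, 0.1)),
    depth = depth, alt_reads = alt_reads,
    vaf = alt_reads / depth,
    maf = ifelse(runif(n) < 0.5, runif(n, 0, 0.5), NA_real_),
    consequence = sample(CONSEQ, n, TRUE),
    score = runif(n),
    loh = NA,
    stringsAsFactors = FALSE))
}

phen <- function(ids, ic50) {
  data.frame(sample_id = ids, ic50 = ic50, stringsAsFactors = FALSE)
}

# --- oracles -----------------------------------------------------------

# two-sided rank-sum p by explicit enumeration of every label
# assignment: assign n1 of the pooled values to group 1, recompute the
# rank sum each time in a plain loop
oracle_ranksum <- function(x, y) {
  pooled <- c(x, y)
  N <- length(pooled); n1 <- length(x)
  r <- rank(pooled)
  center <- n1 * (N + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - center)
  sets <- combn(N, n1)
  hits <- 0L
  for (k in seq_len(ncol(sets))) {
    w <- 0
    for (i in sets[, k]) w <- w + r[i]
    if (abs(w - center) >= obs - 1e-9) hits <- hits + 1L
  }
  hits / ncol(sets)
}

# two-sided Fisher p by full hypergeometric enumeration
# (minimum-likelihood rule) for a 2x2 matrix of counts
oracle_fisher <- function(tab) {
  col1 <- sum(tab[, 1]); col2 <- sum(tab[, 2]); row1 <- sum(tab[1, ])
  xs <- max(0L, row1 - col2):min(row1, col1)
  probs <- dhyper(xs, col1, col2, row1)
  obs <- dhyper(tab[1, 1], col1, col2, row1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
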