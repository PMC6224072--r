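test_that("mutation status is one-or-more-variants in the set", {
  set_fa <- gene_set("FA", c("FANCA", "BRCA2"))
  ph <- phen(c("S1", "S2", "S3"), c(1, 2, 3))
  v <- vtab(vrow(sample_id = "S1", gene = "FANCA"),
            vrow(sample_id = "S2", gene = "OTHER"))
  st <- assign_status(v, set_fa, ph)
  expect_equal(st$mutated, c(TRUE, FALSE, FALSE))
  expect_equal(st$sample_id, ph$sample_id)
  expect_identical(names(attr(st, "supporting")), "S1")
  # mutated <=> at least one supporting variant
  expect_equal(st$mutated, st$n_support > 0L)

  # empty variant list: everyone non-mutated
  st0 <- assign_status(v[0, ], set_fa, ph)
  expect_false(any(st0$mutated))

  # a variant in an unknown sample is an error
  v_bad <- vtab(vrow(sample_id = "SX", gene = "FANCA"))
  expect_error(assign_status(v_bad, set_fa, ph), "SX")
})

test_that("rank-sum association matches the worked example and omits", {
  st <- data.frame(sample_id = paste0("S", 1:5),
                   mutated = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  ph <- phen(paste0("S", 1:5), c(1, 2, 3, 4, 5))
  res <- ranksum_association(st, ph)
  expect_equal(res$p_value, 0.2)  # 2 of the C(5,3) splits are as extreme
  expect_equal(res$delta_ic50, mean(1:3) - mean(4:5))
  expect_false(res$omitted)

  # a single mutated sample is below the minimum group size
  st1 <- data.frame(sample_id = paste0("S", 1:5),
                    mutated = c(TRUE, rep(FALSE, 4)))
  res1 <- ranksum_association(st1, ph)
  expect_true(res1$omitted)
  expect_true(is.na(res1$p_value))
  expect_false(is.na(res1$delta_ic50))

  # all samples in one group: omitted, not an error
  st_all <- data.frame(sample_id = paste0("S", 1:5), mutated = TRUE)
  expect_true(ranksum_association(st_all, ph)$omitted)

  # fully tied data in a symmetric split has maximal p
  st2 <- data.frame(sample_id = paste0("S", 1:4),
                    mutated = c(TRUE, TRUE, FALSE, FALSE))
  ph2 <- phen(paste0("S", 1:4), rep(2.5, 4))
  expect_equal(ranksum_association(st2, ph2)$p_value, 1)
})

test_that("exact rank-sum agrees with enumeration for all small splits", {
  set.seed(7)
  for (n1 in 2:4) {
    for (n2 in 2:4) {
      x <- sample(1:6, n1, replace = TRUE)  # ties likely
      y <- sample(1:6, n2, replace = TRUE)
      expect_equal(repairscan:::ranksum_p(x, y), oracle_ranksum(x, y),
                   info = paste(n1, n2))
      # tie-free case also matches R's exact Wilcoxon
      xs <- runif(n1); ys <- runif(n2)
      expect_equal(repairscan:::ranksum_p(xs, ys),
                   wilcox.test(xs, ys, exact = TRUE)$p.value)
    }
  }
})

test_that("PPV counts mutated samples among the most sensitive", {
  ids <- sprintf("S%02d", 1:29)
  ph <- phen(ids, seq_len(29))
  # ten mutated samples occupying the ten lowest IC50s
  st <- data.frame(sample_id = ids, mutated = seq_len(29) <= 10)
  expect_equal(ppv(st, ph, top_k = 10), 1.0)
  # everyone mutated: 10/29
  st_all <- data.frame(sample_id = ids, mutated = TRUE)
  expect_equal(ppv(st_all, ph, top_k = 10), 10 / 29)
  # the alternative denominator reading
  expect_equal(ppv(st_all, ph, top_k = 10, denominator = "top_k"), 1.0)
  # no mutated samples: undefined
  st_none <- data.frame(sample_id = ids, mutated = FALSE)
  expect_true(is.na(ppv(st_none, ph)))
  # boundary ties are resolved deterministically and reported
  ph_tie <- phen(ids, c(seq_len(10), 10, seq(12, 29)))
  expect_message(ppv(st_all, ph_tie, top_k = 10), "tie")
})

test_that("label-randomized PPV averages top_k / n_samples", {
  set.seed(31)
  ids <- sprintf("S%02d", 1:29)
  ph <- phen(ids, rlnorm(29))
  draws <- replicate(4000, {
    st <- data.frame(sample_id = ids,
                     mutated = seq_len(29) %in% sample.int(29, 7))
    ppv(st, ph, top_k = 10)
  })
  expected <- 10 / 29
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 3 * se + 1e-12)
})

test_that("threshold sweeps nest their mutated sets and flag omissions", {
  sim <- simulate_panel(panel_spec(seed = 5))
  v <- restrict_consequences(apply_call_filters(sim$variants))
  cfg <- run_config(vaf_grid = seq(0, 0.9, 0.15),
                    maf_grid = c(0, 0.01, 0.2, NA))
  sw <- sweep_association(v, sim$pathway, sim$phenotypes, cfg,
                          axis = "vaf")
  expect_s3_class(sw, "assoc_sweep")
  expect_equal(nrow(sw), length(cfg$vaf_grid))
  # retained variants and mutated samples shrink as thresholds rise
  expect_true(all(diff(sw$n_retained) <= 0))
  expect_true(all(diff(sw$n_mutated) <= 0))
  expect_equal(sw$omitted, is.na(sw$p_value))

  # stricter thresholds give mutated sets nested in looser ones
  for (i in seq_len(nrow(sw) - 1)) {
    loose <- assign_status(vaf_select(v, sw$vaf_threshold[i]),
                           sim$pathway, sim$phenotypes)
    strict <- assign_status(vaf_select(v, sw$vaf_threshold[i + 1]),
                            sim$pathway, sim$phenotypes)
    expect_true(all(strict$sample_id[strict$mutated] %in%
                      loose$sample_id[loose$mutated]))
  }

  both <- sweep_association(v, sim$pathway, sim$phenotypes, cfg,
                            axis = "both")
  expect_equal(nrow(both), length(cfg$vaf_grid) * length(cfg$maf_grid))
})

test_that("zygosity+rarity filtering sharpens the planted association", {
  hits <- 0L
  for (s in 1:20) {
    sim <- simulate_panel(panel_spec(seed = 4000 + s))
    v <- restrict_consequences(apply_call_filters(sim$variants))
    strict <- pathway_association(v, sim$pathway, sim$phenotypes,
                                  vaf_threshold = 0.8,
                                  maf_threshold = 0.01)
    loose <- pathway_association(v, sim$pathway, sim$phenotypes,
                                 maf_threshold = 0.01)
    if (!is.na(strict$p_value) && !is.na(loose$p_value) &&
        strict$p_value < loose$p_value) hits <- hits + 1L
  }
  expect_gt(hits, 10L)  # majority of seeds
})

test_that("random gene sets are length-matched and exclude the pathway", {
  set.seed(13)
  ann <- as_gene_annotation(data.frame(
    gene = sprintf("G%03d", 1:200),
    length = round(exp(runif(200, log(500), log(10000)))),
    chrom = as.character(rep(1:10, each = 20)),
    order_index = rep(1:20, 10)))
  target <- 40000
  sets <- random_gene_sets(ann, target, n = 100, tolerance = 0.10,
                           exclude = c("G001", "G002"), seed = 77)
  lens <- vapply(sets, `[[`, 1, "cumulative_length")
  expect_true(all(lens >= target * 0.9 & lens <= target * 1.1))
  expect_false(any(vapply(sets, function(s)
    any(c("G001", "G002") %in% s$genes), NA)))
  # genes are unique within a set
  expect_true(all(vapply(sets, function(s)
    !anyDuplicated(s$genes), NA)))
  # a singleton set is valid when one gene matches the target exactly
  one <- as_gene_annotation(data.frame(gene = "A", length = 1234,
                                       chrom = "1", order_index = 1L))
  s1 <- random_gene_sets(one, 1234, n = 3, tolerance = 0)
  expect_true(all(vapply(s1, function(s)
    identical(s$genes, "A"), NA)))
  # unreachable targets error, reporting the tolerance
  expect_error(random_gene_sets(one, 10, n = 1, tolerance = 0.1,
                                max_retries = 5), "tolerance")
})

test_that("nearest-gene control picks closest non-members per chromosome", {
  ann <- as_gene_annotation(data.frame(
    gene = c("M1", "A", "B", "M2", "C"),
    length = c(100, 200, 300, 400, 500),
    chrom = "1",
    order_index = c(5L, 4L, 7L, 3L, 1L)))
  gs <- gene_set("P", c("M1", "M2"))
  ctrl <- nearest_gene_control(ann, gs)
  # M1 at 5: non-members at 4 (A) and 7 (B) -> A (distance 1 beats 2)
  # M2 at 3: A at distance 1 again -> shared neighbor appears once
  expect_identical(ctrl$genes, "A")
  expect_error(nearest_gene_control(ann, gene_set("Q", "ZZ")), "ZZ")

  # equidistant tie goes to the lower order index
  ann2 <- as_gene_annotation(data.frame(
    gene = c("M", "L", "R"), length = c(1, 1, 1), chrom = "1",
    order_index = c(5L, 4L, 6L)))
  expect_identical(nearest_gene_control(ann2, gene_set("P", "M"))$genes,
                   "L")
})

test_that("nearest-gene control shows no association on planted panels", {
  signif <- 0L
  for (s in 1:20) {
    sim <- simulate_panel(panel_spec(seed = 6000 + s))
    v <- restrict_consequences(apply_call_filters(sim$variants))
    ctrl <- nearest_gene_control(sim$annotation, sim$pathway)
    res <- pathway_association(v, ctrl, sim$phenotypes,
                               vaf_threshold = 0.8,
                               maf_threshold = 0.01)
    if (!is.na(res$p_value) && res$p_value < 0.05) signif <- signif + 1L
  }
  expect_lte(signif, 4L)
})
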