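make_screen_fixture <- function(seed = 1) {
  sim <- simulate_panel(panel_spec(seed = seed))
  v <- restrict_consequences(apply_call_filters(sim$variants))
  paths <- simulate_pathway_collection(sim$annotation, sim$pathway,
                                       n_decoys = 15, seed = seed)
  list(sim = sim, v = v, paths = paths)
}

test_that("screen associates every pathway and flags empty ones", {
  fx <- make_screen_fixture(21)
  # add a pathway whose genes never occur in the variant table
  paths <- c(fx$paths,
             list(ghost = gene_set("ghost", c("NOPE1", "NOPE2"))))
  rows <- screen_pathways(fx$v, paths, fx$sim$phenotypes,
                          vaf_threshold = 0.8, maf_threshold = 0.01,
                          prune = FALSE)
  expect_s3_class(rows, "pathway_screen")
  expect_equal(nrow(rows), length(paths))
  ghost <- rows[rows$pathway == "ghost", ]
  expect_equal(ghost$n_mutated, 0L)
  expect_true(ghost$omitted)
  expect_true(is.na(ghost$p_value))
  # mutation profiles are aligned to samples x pathways
  prof <- attr(rows, "profiles")
  expect_equal(dim(prof), c(nrow(fx$sim$phenotypes), length(paths)))
  expect_true(all(prof %in% c(0L, 1L)))
})

test_that("screen ranking is invariant to pathway input order", {
  fx <- make_screen_fixture(22)
  r1 <- screen_pathways(fx$v, fx$paths, fx$sim$phenotypes, prune = FALSE)
  r2 <- screen_pathways(fx$v, rev(fx$paths), fx$sim$phenotypes,
                        prune = FALSE)
  o1 <- r1[order(r1$pathway), c("pathway", "n_mutated", "p_value")]
  o2 <- r2[order(r2$pathway), c("pathway", "n_mutated", "p_value")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("correlated profiles prune the weaker association", {
  rows <- data.frame(pathway = c("A", "B", "C"),
                     n_mutated = c(5L, 5L, 4L),
                     p_value = c(0.01, 0.20, 0.50),
                     delta_ic50 = c(-1, -1, 0),
                     omitted = FALSE, pruned = FALSE,
                     pruned_by = NA_character_,
                     stringsAsFactors = FALSE)
  prof_id <- c(1, 1, 1, 0, 0, 0, 1, 1, 0, 0)
  profiles <- cbind(A = prof_id, B = prof_id,
                    C = c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1))
  out <- prune_correlated(rows, profiles, 0.75)
  expect_equal(out$pruned, c(FALSE, TRUE, FALSE))
  expect_equal(out$pruned_by[2], "A")
  # a rho = 0.5-ish pair survives
  expect_false(out$pruned[3])

  # three mutually identical profiles leave exactly one survivor
  profiles3 <- cbind(A = prof_id, B = prof_id, C = prof_id)
  out3 <- prune_correlated(rows, profiles3, 0.75)
  expect_equal(sum(!out3$pruned), 1L)
  expect_equal(out3$pathway[!out3$pruned], "A")
})

test_that("greedy pruning matches a brute-force reference on small sets", {
  # independent reference: repeatedly take the smallest-p unpruned row,
  # prune its correlated neighbors, recurse on the rest
  ref_prune <- function(p, profmat, thr) {
    survivors <- character()
    remaining <- order(p, names(p))
    names_left <- names(p)[remaining]
    while (length(names_left) > 0) {
      best <- names_left[1]
      survivors <- c(survivors, best)
      keep <- vapply(names_left[-1], function(nm) {
        a <- profmat[, best]; b <- profmat[, nm]
        if (sd(a) == 0 || sd(b) == 0) {
          !identical(as.integer(a), as.integer(b))
        } else cor(a, b) < thr
      }, NA)
      names_left <- names_left[-1][keep]
    }
    sort(survivors)
  }
  set.seed(55)
  for (i in 1:20) {
    k <- 5L; n <- 12L
    profiles <- matrix(rbinom(n * k, 1, 0.5), n, k,
                       dimnames = list(NULL, LETTERS[1:k]))
    # force some duplicated profiles
    profiles[, 2] <- profiles[, 1]
    if (i %% 2 == 0) profiles[, 4] <- profiles[, 3]
    p <- round(runif(k), 3)
    rows <- data.frame(pathway = LETTERS[1:k], n_mutated = colSums(profiles),
                       p_value = p, delta_ic50 = 0, omitted = FALSE,
                       pruned = FALSE, pruned_by = NA_character_,
                       stringsAsFactors = FALSE)
    out <- prune_correlated(rows, profiles, 0.75)
    expect_equal(sort(out$pathway[!out$pruned]),
                 ref_prune(setNames(p, LETTERS[1:k]), profiles, 0.75))
    # every pruned row names a surviving, stronger pruner
    for (j in which(out$pruned)) {
      by <- out$pruned_by[j]
      expect_false(out$pruned[out$pathway == by])
      expect_lte(out$p_value[out$pathway == by], out$p_value[j])
    }
  }
})

test_that("pruning never removes the smallest p and can be disabled", {
  fx <- make_screen_fixture(23)
  rows <- screen_pathways(fx$v, fx$paths, fx$sim$phenotypes,
                          prune = TRUE, corr_threshold = 0.75)
  best <- which.min(rows$p_value)
  expect_false(rows$pruned[best])
  # a threshold above 1 never prunes anything
  none <- prune_correlated(rows, attr(rows, "profiles"),
                           corr_threshold = 1.5)
  expect_false(any(none$pruned))
})

test_that("optional BH adjustment adds a monotone adjusted column", {
  fx <- make_screen_fixture(25)
  rows <- screen_pathways(fx$v, fx$paths, fx$sim$phenotypes,
                          prune = FALSE, p_adjust = "BH")
  ok <- !is.na(rows$p_value)
  expect_true(all(rows$p_adjusted[ok] >= rows$p_value[ok]))
  none <- screen_pathways(fx$v, fx$paths, fx$sim$phenotypes,
                          prune = FALSE)
  expect_false("p_adjusted" %in% names(none))
})

test_that("constant profiles only pair with identical profiles", {
  rows <- data.frame(pathway = c("A", "B", "C"), n_mutated = c(4L, 4L, 0L),
                     p_value = c(0.1, 0.2, NA), delta_ic50 = 0,
                     omitted = c(FALSE, FALSE, TRUE), pruned = FALSE,
                     pruned_by = NA_character_, stringsAsFactors = FALSE)
  allmut <- rep(1, 4)
  profiles <- cbind(A = allmut, B = allmut, C = rep(0, 4))
  out <- prune_correlated(rows, profiles, 0.75)
  expect_equal(out$pruned, c(FALSE, TRUE, FALSE))  # C (all zero) untouched
})

test_that("status overrides change pathway mutation before screening", {
  fx <- make_screen_fixture(24)
  target_gene <- fx$sim$pathway$genes[1]
  mut_samples <- unique(fx$v$sample_id[fx$v$gene %in%
                                         fx$sim$pathway$genes])
  off <- data.frame(sample_id = mut_samples,
                    gene = rep(fx$sim$pathway$genes,
                               each = length(mut_samples)),
                    mutated = FALSE, stringsAsFactors = FALSE)
  rows <- screen_pathways(fx$v, fx$paths["planted_pathway"],
                          fx$sim$phenotypes, override = off,
                          prune = FALSE)
  expect_equal(rows$n_mutated, 0L)

  on <- data.frame(sample_id = fx$sim$phenotypes$sample_id[1:3],
                   gene = target_gene, mutated = TRUE,
                   stringsAsFactors = FALSE)
  rows_on <- screen_pathways(fx$v[0, ], fx$paths["planted_pathway"],
                             fx$sim$phenotypes, override = on,
                             prune = FALSE)
  expect_equal(rows_on$n_mutated, 3L)
})

test_that("volcano table transforms, orders and keeps pruned rows", {
  rows <- data.frame(pathway = c("B", "A", "C"),
                     n_mutated = c(3L, 5L, 0L),
                     p_value = c(0.01, 0.01, NA),
                     delta_ic50 = c(-2, -1, 0),
                     omitted = c(FALSE, FALSE, TRUE),
                     pruned = c(FALSE, TRUE, FALSE),
                     pruned_by = c(NA, "B", NA),
                     stringsAsFactors = FALSE)
  vt <- volcano_table(rows)
  expect_equal(vt$neg_log10_p[1:2], c(2, 2))
  expect_equal(vt$pathway, c("A", "B", "C"))  # tie broken by name, NA last
  expect_true(is.na(vt$neg_log10_p[3]))       # omitted row kept, blank y
  expect_true(any(vt$pruned))                 # pruned rows flagged, not dropped
  path <- withr::local_tempfile(fileext = ".tsv")
  volcano_table(rows, path = path)
  expect_equal(read_results(path)$pathway, vt$pathway)
})
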