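test_that("read-depth filter keeps samples at or above the threshold", {
  tab <- toy_table(cbind(c(5000, 0), c(9998, 1), c(5000, 5000), c(10000, 10000)))
  out <- filter_samples(tab, min_reads = 10000)
  expect_equal(colnames(out), c("s3", "s4"))
  expect_equal(rownames(out), rownames(tab))
  # toy depths 5k, 12k, 15k, 8k, 30k -> s2, s3, s5 retained
  tab5 <- toy_table(rbind(c(2500, 6000, 7500, 4000, 15000),
                          c(2500, 6000, 7500, 4000, 15000)))
  expect_equal(colnames(filter_samples(tab5, 10000)), c("s2", "s3", "s5"))
  expect_identical(filter_samples(tab5, 0), tab5)
  expect_warning(filter_samples(tab5, 1e9), "all samples removed")
})

test_that("rarefaction subsamples without replacement to the exact depth", {
  set.seed(42)
  tab <- toy_table(matrix(rpois(60, 40), nrow = 6))
  depth <- min(colSums(tab)) - 5
  out <- rarefy(tab, depth, seed = 1)
  expect_true(all(colSums(out) == depth))
  expect_true(all(out <= tab))                       # without replacement
  # sample with exactly `depth` reads passes through unchanged
  exact <- toy_table(cbind(c(30L, 70L)))
  expect_equal(unname(rarefy(exact, 100, seed = 1)), unname(exact))
  # shallow samples are dropped
  mix <- toy_table(cbind(c(50L, 50L), c(10L, 10L)))
  expect_equal(colnames(rarefy(mix, 50, seed = 1)), "s1")
  # hypergeometric moments: (100, 100) rarefied to 100 -> mean ~ 50
  two <- toy_table(cbind(c(100L, 100L)))
  reps <- vapply(1:500, function(s) rarefy(two, 100, seed = s)[1, 1], numeric(1))
  hyper_sd <- sqrt(100 * 0.5 * 0.5 * 100 / 199)
  expect_lt(abs(mean(reps) - 50), 3 * hyper_sd / sqrt(500))
})

test_that("genus collapsing sums by genus and labels unresolved taxa by deepest rank", {
  tab <- toy_table(matrix(c(5L, 7L, 2L, 3L, 1L, 4L), ncol = 1),
                   taxa = sprintf("f%d", 1:6))
  taxonomy <- data.frame(
    feature_id = sprintf("f%d", 1:6),
    lineage = c("k__B; p__P; c__C; o__O; f__F1; g__G1; s__x",
                "k__B; p__P; c__C; o__O; f__F1; g__G1; s__y",
                "k__B; p__P; c__C; o__O; f__F2; g__G2; s__z",
                "k__B; p__P; c__C; o__O; f__F2; g__G2; s__w",
                "k__B; p__P; c__C; o__O; f__F3",
                "k__B"))
  out <- collapse_genus(tab, taxonomy)
  expect_equal(sum(out), sum(tab))                   # conservation
  expect_equal(out["g__G1", 1], 12L)
  expect_equal(out["g__G2", 1], 5L)
  expect_true("f__F3 (unresolved)" %in% rownames(out))
  expect_true("k__B (unresolved)" %in% rownames(out))
  expect_error(collapse_genus(tab, taxonomy[-1, ]), "f1")
})

test_that("rare-taxon filter drops prevalence below the threshold", {
  prev <- c(1, 4, 5, 9)
  tab <- toy_table(t(sapply(prev, function(p) c(rep(1L, p), rep(0L, 20 - p)))))
  out <- filter_rare_taxa(tab, min_samples = 5)
  expect_equal(rownames(out), c("t3", "t4"))         # 2 of 4 survive
  expect_identical(nrow(filter_rare_taxa(tab, 0)), 4L)
})

test_that("low-abundance taxa fold into Other with totals conserved", {
  tab <- toy_table(matrix(c(9000L, 900L, 90L, 10L), ncol = 1))
  # threshold 0.01% of 10,000 = 1 count: nothing folds
  out1 <- group_other_taxa(tab, 1e-4)
  expect_false("Other" %in% rownames(out1))
  expect_identical(attr(out1, "fraction_other"), 0)
  # threshold 1%: taxa with 90 and 10 fold, Other = 100
  out2 <- suppressMessages(group_other_taxa(tab, 0.01))
  expect_equal(out2["Other", 1], 100L)
  expect_equal(sum(out2), sum(tab))
  expect_equal(attr(out2, "fraction_other"), 0.01)
  # zero-count taxon folds under any positive threshold
  tabz <- toy_table(matrix(c(100L, 0L), ncol = 1))
  outz <- suppressMessages(group_other_taxa(tabz, 1e-6))
  expect_true("Other" %in% rownames(outz))
})

test_that("clr transform has closed forms, closure and scale invariance", {
  expect_equal(clr_transform(c(1, 1, 1, 1)), c(0, 0, 0, 0))
  expect_equal(clr_transform(c(exp(1), 1, 1)), c(2 / 3, -1 / 3, -1 / 3))
  set.seed(7)
  for (i in 1:20) {
    x <- rgamma(8, 2)
    expect_equal(sum(clr_transform(x)), 0, tolerance = 1e-12)
    expect_equal(clr_transform(3.7 * x), clr_transform(x))  # compositional invariance
  }
  expect_error(clr_transform(c(1, 0, 2)), "positive")
})

test_that("dirichlet instances respect closure, moments and determinism", {
  zero <- toy_table(matrix(c(0L, 0L, 0L), ncol = 1))
  inst <- dirichlet_instances(zero, n_instances = 5, seed = 1)
  expect_length(inst, 5)
  for (i in inst) expect_equal(colSums(i$values), 0, ignore_attr = TRUE, tolerance = 1e-9)
  # Dirichlet moments: counts (1000, 1000), prior 0.5 -> first share ~ 0.5
  tab <- toy_table(matrix(c(1000L, 1000L), ncol = 1))
  inst <- dirichlet_instances(tab, n_instances = 1000, seed = 2)
  shares <- vapply(inst, function(i) {
    p <- exp(i$values[, 1]); (p / sum(p))[1]
  }, numeric(1))
  dir_sd <- sqrt(0.25 / 2002)
  expect_lt(abs(mean(shares) - 0.5), 3 * dir_sd / sqrt(1000))
  # determinism
  a <- dirichlet_instances(tab, n_instances = 3, seed = 9)
  b <- dirichlet_instances(tab, n_instances = 3, seed = 9)
  expect_identical(a, b)
  expect_error(dirichlet_instances(matrix(nrow = 2, ncol = 0)), "empty")
})

test_that("association preprocessing chain applies the documented filter order", {
  set.seed(3)
  des <- simulation_design(n_animals_per_group = c(CON = 1, ABX = 1, ABXFT = 0),
                           n_taxa = 20, depth_range = c(12000, 15000), seed = 3)
  tr <- synthetic_truth(20, n_positive_pairs = 1, n_negative_pairs = 0, seed = 3)
  sim <- simulate_counts(des, tr, seed = 3)
  tt <- simulate_tree_and_taxonomy(20, seed = 3)
  out <- prepare_association_input(sim$counts, sim$metadata, tt$taxonomy)
  expect_equal(out$log$step,
               c("input", "drop_pretreatment", "filter_rare_taxa",
                 "collapse_genus", "group_other_taxa"))
  expect_true(all(out$metadata$phase != "pretreatment"))
  # collapse conserves counts within the retained samples
  expect_equal(out$log$total[4], out$log$total[3])
})
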