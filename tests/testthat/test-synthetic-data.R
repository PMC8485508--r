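test_that("design and truth constructors enforce their invariants", {
  expect_error(simulation_design(sampling_days = c(0, 0, 1)), "strictly increasing")
  expect_error(simulation_design(depth_range = c(0, 10)), "depth_range")
  expect_error(simulation_design(n_taxa = 2), "n_taxa")
  tr <- synthetic_truth(20, seed = 1)
  expect_equal(tr$true_correlation, t(tr$true_correlation))
  expect_equal(diag(tr$true_correlation), rep(1, 20))
  expect_gte(min(eigen(tr$true_correlation, only.values = TRUE)$values), -1e-8)
  expect_true(all(tr$resistant_taxa %in% seq_len(20)))
  expect_error(synthetic_truth(5, n_positive_pairs = 3, n_negative_pairs = 1),
               "disjoint pairs")
  # non-PSD truth rejected by the generator
  bad <- synthetic_truth(6, n_positive_pairs = 0, n_negative_pairs = 0, seed = 1)
  bad$true_correlation[1, 2] <- bad$true_correlation[2, 1] <- 2
  expect_error(simulate_counts(simulation_design(n_taxa = 6), bad),
               "positive semi-definite")
})

test_that("random trees are rooted binary with positive branch lengths and taxonomy matches", {
  out <- simulate_tree_and_taxonomy(3, seed = 1)
  expect_equal(length(out$tree$tip.label), 3)
  expect_equal(nrow(out$tree$edge), 4)               # rooted binary, 3 leaves
  expect_true(all(out$tree$edge.length > 0))
  expect_true(ape::is.rooted(out$tree))
  # determinism: same seed -> byte-identical Newick
  nwk1 <- ape::write.tree(simulate_tree_and_taxonomy(25, seed = 7)$tree)
  nwk2 <- ape::write.tree(simulate_tree_and_taxonomy(25, seed = 7)$tree)
  expect_identical(nwk1, nwk2)
  # unassigned fraction: 50 taxa at 0.1 -> exactly 5 kingdom-only lineages
  tt <- simulate_tree_and_taxonomy(50, seed = 3, fraction_unassigned = 0.1)
  expect_equal(sum(tt$taxonomy$lineage == "k__Bacteria"), 5)
  # shared genera exist so collapsing has work to do
  genera <- sub(".*(g__Genus[0-9]+).*", "\\1",
                grep("g__", tt$taxonomy$lineage, value = TRUE))
  expect_true(any(table(genera) > 1))
  expect_error(simulate_tree_and_taxonomy(2), "at least 3")
})

test_that("simulated counts respect depths, phases and determinism", {
  des <- simulation_design(n_animals_per_group = c(CON = 1, ABX = 1, ABXFT = 1),
                           n_taxa = 15, depth_range = c(5000, 8000), seed = 5)
  tr <- synthetic_truth(15, n_positive_pairs = 1, n_negative_pairs = 1, seed = 5)
  sim <- simulate_counts(des, tr, seed = 5)
  expect_equal(ncol(sim$counts), 3 * length(des$sampling_days))
  expect_true(all(colSums(sim$counts) >= 5000 & colSums(sim$counts) <= 8000))
  expect_equal(colSums(sim$counts), sim$metadata$depth, ignore_attr = TRUE)
  expect_equal(sim$metadata$phase,
               phase_of_day(sim$metadata$day, des$perturbation_window))
  sim2 <- simulate_counts(des, tr, seed = 5)
  expect_identical(sim$counts, sim2$counts)
  # exported latent CLR trajectories are column-centered (CLR identifiability)
  siml <- simulate_counts(des, tr, export_latent = TRUE, seed = 5)
  for (m in siml$latent_clr) expect_equal(colMeans(m), colMeans(m) * 0, tolerance = 1e-12)
  expect_identical(siml$counts, sim$counts)          # export flag changes nothing else
})

test_that("planted latent correlation shows up in exported CLR trajectories", {
  cors <- numeric(20)
  for (s in 1:20) {
    des <- simulation_design(n_animals_per_group = c(CON = 1, ABX = 0, ABXFT = 0),
                             n_taxa = 10, depth_range = c(5000, 6000), seed = s)
    tr <- synthetic_truth(10, n_positive_pairs = 1, n_negative_pairs = 0,
                          strong_rho = 0.9, seed = s)
    sim <- simulate_counts(des, tr, export_latent = TRUE, seed = s)
    ij <- tr$planted_pairs[1, ]
    m <- sim$latent_clr[[1]]
    cors[s] <- cor(m[ij[1], ], m[ij[2], ])
  }
  expect_gt(mean(cors), 0.5)
})

test_that("the antibiotic crash lowers susceptible taxa in treated animals", {
  lower <- 0; n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    des <- simulation_design(n_animals_per_group = c(CON = 0, ABX = 1, ABXFT = 0),
                             sampling_days = c(-6, -4, -2, 0, 2, 3, 4, 6),
                             n_taxa = 20, depth_range = c(10000, 12000), seed = s)
    tr <- synthetic_truth(20, n_positive_pairs = 0, n_negative_pairs = 0, seed = s)
    sim <- simulate_counts(des, tr, seed = s)
    susceptible <- setdiff(tr$perturbed_taxa, tr$resistant_taxa)
    rel <- sweep(sim$counts, 2, colSums(sim$counts), "/")
    md <- sim$metadata
    at <- function(d) sum(rel[susceptible, md$sample_id[md$day == d]])
    if (at(3) < at(-4)) lower <- lower + 1
  }
  expect_gte(lower, 0.9 * n_seeds)
})

test_that("a null design plants no group differences in diversity", {
  des <- simulation_design(n_animals_per_group = c(CON = 2, ABX = 2, ABXFT = 2),
                           sampling_days = c(-6, -4, 0, 4, 8, 13),
                           n_taxa = 25, depth_range = c(10000, 12000),
                           perturbation_effect = 0, seed = 9)
  tr <- synthetic_truth(25, n_positive_pairs = 0, n_negative_pairs = 0, seed = 9)
  sim <- simulate_counts(des, tr, seed = 9)
  H <- shannon(sim$counts)
  md <- sim$metadata
  # animals, not samples, are the replication unit of a group mean
  animal_means <- tapply(H[md$sample_id], md$animal_id, mean)
  grp <- tapply(md$group, md$animal_id, function(x) x[1])[names(animal_means)]
  means <- tapply(animal_means, grp, mean)
  sd_a <- sd(animal_means)
  expect_lt(max(means) - min(means), 3 * sd_a * sqrt(1 / 2 + 1 / 2))
})

test_that("simulated resistomes carry the planted beta-lactam treatment signal", {
  des <- simulation_design(n_animals_per_group = c(CON = 1, ABX = 1, ABXFT = 0),
                           sampling_days = c(-6, -4, 0, 4, 6, 13), seed = 11)
  rt <- simulate_resistome(des, seed = 11)
  expect_equal(sort(unique(rt$family_map$family)),
               sort(c("Tetracycline", "Beta-lactam", "Aminoglycoside", "Macrolide",
                      "Vancomycin", "MDR", "Sulphonamide")))
  expect_equal(nrow(rt$genes), 83)
  expect_true(all(rt$totals >= colSums(rt$genes)))
  # determinism
  rt2 <- simulate_resistome(des, seed = 11)
  expect_identical(rt$genes, rt2$genes)
  # enrichment: beta-lactam proportion higher at day 6 than day -4 for ABX
  up <- 0; n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    r <- simulate_resistome(des, seed = 100 + s)
    pr <- family_proportions(r)
    if (pr["Beta-lactam", "ABX1_d6"] > pr["Beta-lactam", "ABX1_d-4"]) up <- up + 1
  }
  expect_gte(up, 0.9 * n_seeds)
  # null enrichment: proportions equal across groups within MC error
  r0 <- simulate_resistome(des, treatment_enrichment = 1, abr_load_enrichment = 1,
                           seed = 12)
  pr0 <- family_proportions(r0)
  md <- r0$metadata
  bl <- pr0["Beta-lactam", ]
  diffm <- abs(mean(bl[md$group == "ABX"]) - mean(bl[md$group == "CON"]))
  expect_lt(diffm, 3 * sd(bl) / sqrt(6))
})
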