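# fixtures built in code: toy count tables, small trees, fake posteriors

toy_table <- function(values, taxa = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- taxa %||% sprintf("t%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

star_tree3 <- function() ape::read.tree(text = "(t1:1,t2:1,t3:1);")

fake_posterior <- function(draws_array, taxon_ids = NULL) {
  D <- dim(draws_array)[1]
  structure(list(draws = draws_array,
                 taxon_ids = taxon_ids %||% sprintf("t%d", seq_len(D)),
                 config = gp_config(), provenance = list()),
            class = "gp_posterior")
}

# fake CLR instance (fields as produced by dirichlet_instances)
fake_instance <- function(values, days, animal_id = "a1", instance_index = 1L) {
  structure(list(values = values, instance_index = instance_index,
                 animal_id = animal_id, days = days),
            class = "clr_instance")
}

# brute-force unweighted UniFrac oracle: loops over every edge and tests
# descendant-leaf presence via phytools, independent of the package's
# postorder accumulation
oracle_unifrac <- function(table, tree) {
  n <- ncol(table)
  pres <- table > 0
  d <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  edge_tips <- lapply(seq_len(nrow(tree$edge)), function(i) {
    node <- tree$edge[i, 2]
    desc <- if (node <= length(tree$tip.label)) node
            else phytools::getDescendants(tree, node)
    tree$tip.label[desc[desc <= length(tree$tip.label)]]
  })
  in_sample <- function(tips, s) {
    tips <- intersect(tips, rownames(table))
    length(tips) > 0 && any(pres[tips, s])
  }
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    uniq <- 0; union <- 0
    for (i in seq_along(edge_tips)) {
      ina <- in_sample(edge_tips[[i]], a)
      inb <- in_sample(edge_tips[[i]], b)
      if (ina || inb) union <- union + tree$edge.length[i]
      if (xor(ina, inb)) uniq <- uniq + tree$edge.length[i]
    }
    d[a, b] <- d[b, a] <- if (union > 0) uniq / union else 0
  }
  d
}

# one-group longitudinal series for trajectory tests
sim_series <- function(n_animals, days, group_fun, animal_sd = 0.5,
                       noise_sd = 1, groups = c("A", "B")) {
  out <- list()
  for (g in groups) for (a in seq_len(n_animals)) {
    id <- paste0(g, a)
    eff <- rnorm(1, 0, animal_sd)
    out[[id]] <- data.frame(
      day = days, value = group_fun(g, days) + eff + rnorm(length(days), 0, noise_sd),
      animal = id, group = g)
  }
  do.call(rbind, out)
}

# small simulated group for association tests: returns CLR instances
sim_group_instances <- function(seed, n_taxa, n_animals, n_pos = 0, n_neg = 0,
                                n_instances = 32, days = seq(8, 36, by = 2),
                                perturbation_effect = 0) {
  # base_abundance_sd = 1 emulates the narrower abundance range of the
  # post-filter genus table the association engine operates on
  des <- simulation_design(
    n_animals_per_group = c(CON = 0, ABX = n_animals, ABXFT = 0),
    sampling_days = days, n_taxa = n_taxa,
    depth_range = c(15000, 20000), base_abundance_sd = 1,
    perturbation_effect = perturbation_effect, seed = seed)
  tr <- synthetic_truth(n_taxa, n_positive_pairs = n_pos,
                        n_negative_pairs = n_neg, seed = seed)
  sim <- simulate_counts(des, tr, seed = seed)
  md <- sim$metadata
  inst <- list()
  for (an in unique(md$animal_id)) {
    rows <- md[md$animal_id == an, ]
    inst <- c(inst, dirichlet_instances(sim$counts[, rows$sample_id],
                                        days = rows$day,
                                        n_instances = n_instances,
                                        animal_id = an))
  }
  list(instances = inst, truth = tr, sim = sim)
}

planted_pair_keys <- function(truth, ids) {
  apply(truth$planted_pairs, 1, function(p) paste(sort(ids[p]), collapse = "|"))
}

edge_keys <- function(edges) {
  paste(pmin(edges$taxon_i, edges$taxon_j),
        pmax(edges$taxon_i, edges$taxon_j), sep = "|")
}
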