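#' Simulation design for a three-group longitudinal perturbation study
#'
#' Encodes the study conditions the generator emulates: three experimental
#' groups (untreated controls CON, antibiotic-treated ABX, and
#' antibiotic-treated plus fecal transfaunation ABXFT), dense sampling around
#' a 7-day antibiotic course (days 0-6) followed by sparse sampling through a
#' ~4-month recovery, multinomial sequencing counts over a genus-level taxon
#' set, and a group-specific exponential return toward baseline after the
#' perturbation window. Transfaunation (administration of the animal's own
#' pretreatment feces) happens on `transfaunation_day`.
#'
#' @param n_animals_per_group named counts for CON, ABX and ABXFT animals.
#' @param sampling_days strictly increasing integer days; day 0 is the start
#'   of antibiotic treatment.
#' @param n_taxa number of taxa (genus-level features).
#' @param depth_range `c(min, max)` sequencing reads per sample.
#' @param perturbation_window `c(first, last)` day of the antibiotic course.
#' @param perturbation_effect log-abundance shift subtracted from susceptible
#'   taxa of treated animals during the window; scalar or per-taxon vector.
#'   Because counts are compositional, only the shift relative to the
#'   unperturbed (resistant) taxa matters: the default 10 natural-log units
#'   (~4 orders of magnitude, in line with published log-reductions of
#'   susceptible gut taxa under beta-lactams) lets resistant taxa dominate
#'   and pushes typical susceptible taxa below the detection limit of a
#'   15,000-read sample, reproducing the drastic loss of detected taxa that
#'   broad-spectrum antibiotics cause.
#' @param transfaunation_day day the ABXFT animals receive their baseline
#'   community back.
#' @param recovery_rate_by_group named per-day exponential decay rates of the
#'   residual perturbation after the window closes.
#' @param ft_blend_weight convex weight on the day -4 (baseline) latent state
#'   when transfaunation resets the ABXFT community.
#' @param base_abundance_sd spread (log scale) of typical taxon abundances.
#'   The default 2 emulates a raw heavy-tailed feature table whose rare taxa
#'   flicker around the rarefaction detection limit; use 1 to emulate the
#'   narrower abundance range of a genus table after rare-taxon filtering,
#'   the input the association engine actually sees.
#' @param seed integer seed driving all randomness of the design.
#' @return an object of class `simulation_design`.
#' @export
simulation_design <- function(n_animals_per_group = c(CON = 4, ABX = 4, ABXFT = 3),
                              sampling_days = c(-6, -4, -2, 0, 2, 4, 6, 8, 10,
                                                13, 20, 34, 62, 90, 118),
                              n_taxa = 80,
                              depth_range = c(15000, 60000),
                              perturbation_window = c(0, 6),
                              perturbation_effect = 10,
                              transfaunation_day = 7,
                              recovery_rate_by_group = c(CON = 0, ABX = 0.05, ABXFT = 0.2),
                              ft_blend_weight = 0.5,
                              base_abundance_sd = 2,
                              seed = 1L) {
  stopifnot(all(c("CON", "ABX", "ABXFT") %in% names(n_animals_per_group)),
            all(n_animals_per_group >= 0))
  if (any(diff(sampling_days) <= 0))
    stop("invalid design: sampling_days must be strictly increasing")
  if (depth_range[1] < 1 || depth_range[2] < depth_range[1])
    stop("invalid design: depth_range minimum must be >= 1 and range ordered")
  if (n_taxa < 3) stop("invalid design: n_taxa must be >= 3")
  stopifnot(perturbation_window[1] <= perturbation_window[2],
            ft_blend_weight >= 0, ft_blend_weight <= 1)
  structure(list(
    n_animals_per_group = n_animals_per_group[c("CON", "ABX", "ABXFT")],
    sampling_days = sampling_days,
    n_taxa = as.integer(n_taxa),
    depth_range = depth_range,
    perturbation_window = perturbation_window,
    perturbation_effect = perturbation_effect,
    transfaunation_day = transfaunation_day,
    recovery_rate_by_group = recovery_rate_by_group,
    ft_blend_weight = ft_blend_weight,
    base_abundance_sd = base_abundance_sd,
    seed = as.integer(seed)
  ), class = "simulation_design")
}

#' Planted ground truth for the synthetic community
#'
#' Holds everything downstream recovery tests need to know about the
#' generator: the planted taxon-taxon correlation matrix (identity plus
#' disjoint strong pairs), the temporal kernel lengthscale, which taxa the
#' antibiotic suppresses, and which taxa are resistant (their log ratios rise
#' during treatment because everything else crashes, the *Bacteroides* /
#' *Parabacteroides* signature).
#'
#' @param n_taxa number of taxa; must match the design this truth is used with.
#' @param n_positive_pairs,n_negative_pairs planted strong pairs of each sign.
#' @param strong_rho magnitude of planted correlations (default 0.8).
#' @param true_lengthscale temporal kernel bandwidth in days.
#' @param latent_sd marginal standard deviation of latent log abundances.
#' @param resistant_taxa integer indices of antibiotic-resistant taxa; by
#'   default roughly 5\% of taxa, chosen outside the planted pairs.
#' @param perturbed_taxa integer indices the antibiotic suppresses; default
#'   all non-resistant taxa.
#' @param seed seed for the random pair/taxon placement.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(n_taxa,
                            n_positive_pairs = 5,
                            n_negative_pairs = 3,
                            strong_rho = 0.8,
                            true_lengthscale = 10,
                            latent_sd = 1,
                            resistant_taxa = NULL,
                            perturbed_taxa = NULL,
                            seed = 1L) {
  n_taxa <- as.integer(n_taxa)
  n_pairs <- n_positive_pairs + n_negative_pairs
  if (2 * n_pairs > n_taxa)
    stop("invalid truth: not enough taxa to place ", n_pairs, " disjoint pairs")
  set_seed_if(seed)
  idx <- sample.int(n_taxa, 2 * n_pairs)
  pairs <- if (n_pairs > 0) matrix(idx, ncol = 2) else matrix(integer(), ncol = 2)
  rho <- c(rep(strong_rho, n_positive_pairs), rep(-strong_rho, n_negative_pairs))
  R <- diag(n_taxa)
  for (k in seq_len(n_pairs)) {
    R[pairs[k, 1], pairs[k, 2]] <- rho[k]
    R[pairs[k, 2], pairs[k, 1]] <- rho[k]
  }
  if (min_eigen(R) < -1e-8) stop("invalid truth: planted correlation not PSD")
  if (is.null(resistant_taxa)) {
    free <- setdiff(seq_len(n_taxa), idx)
    n_res <- max(1L, round(0.05 * n_taxa))
    resistant_taxa <- if (length(free) >= n_res) sort(sample(free, n_res)) else integer()
  }
  if (!all(resistant_taxa %in% seq_len(n_taxa)))
    stop("invalid truth: resistant_taxa out of range")
  if (is.null(perturbed_taxa)) perturbed_taxa <- setdiff(seq_len(n_taxa), resistant_taxa)
  structure(list(
    n_taxa = n_taxa,
    true_correlation = R,
    planted_pairs = pairs,
    planted_rho = rho,
    true_lengthscale = true_lengthscale,
    latent_sd = latent_sd,
    resistant_taxa = as.integer(resistant_taxa),
    perturbed_taxa = as.integer(perturbed_taxa),
    seed = as.integer(seed)
  ), class = "synthetic_truth")
}

taxon_ids <- function(n) sprintf("taxon_%03d", seq_len(n))

#' Simulate a rooted phylogeny and a QIIME2-style taxonomy for the taxa
#'
#' Draws a random rooted binary tree with positive branch lengths (leaves
#' labelled `taxon_001`, ...) and assigns each leaf a seven-rank lineage.
#' Genera are shared between leaves (several leaves per genus) so the
#' genus-collapsing step has work to do, and a configurable fraction of
#' leaves is left unassigned below Kingdom.
#'
#' @param n_taxa number of leaves, at least 3.
#' @param seed integer seed.
#' @param fraction_unassigned fraction of leaves whose lineage stops at
#'   Kingdom (rounded to a whole number of leaves).
#' @return list with `tree` (an [ape::phylo]) and `taxonomy` (data.frame with
#'   columns `feature_id`, `lineage`).
#' @export
simulate_tree_and_taxonomy <- function(n_taxa, seed = 1L, fraction_unassigned = 0) {
  if (n_taxa < 3) stop("invalid design: need at least 3 taxa for a rooted tree")
  stopifnot(fraction_unassigned >= 0, fraction_unassigned < 1)
  set_seed_if(seed)
  ids <- taxon_ids(n_taxa)
  tree <- ape::rtree(n_taxa, rooted = TRUE, tip.label = ids)
  # rtree branch lengths are runif(0,1); keep them strictly positive
  tree$edge.length <- pmax(tree$edge.length, 1e-6)

  n_un <- round(fraction_unassigned * n_taxa)
  unassigned <- if (n_un > 0) sample(ids, n_un) else character()

  n_genera <- max(1L, floor(n_taxa / 3))
  genus <- sample.int(n_genera, n_taxa, replace = TRUE)
  family <- ceiling(genus / 2)
  order <- ceiling(family / 2)
  class <- ceiling(order / 2)
  phylum <- ceiling(class / 2)
  lineage <- sprintf(
    "k__Bacteria; p__Phylum%d; c__Class%d; o__Order%d; f__Family%d; g__Genus%d; s__%s",
    phylum, class, order, family, genus, sub("taxon_", "sp", ids))
  lineage[ids %in% unassigned] <- "k__Bacteria"
  list(tree = tree,
       taxonomy = data.frame(feature_id = ids, lineage = lineage,
                             stringsAsFactors = FALSE))
}

animal_roster <- function(design) {
  grp <- design$n_animals_per_group
  data.frame(
    animal_id = unlist(lapply(names(grp), function(g) sprintf("%s%d", g, seq_len(grp[[g]])))),
    group = rep(names(grp), times = unlist(grp)),
    stringsAsFactors = FALSE
  )
}

#' Phase label for a study day
#'
#' Pretreatment is day < 0, treatment is the antibiotic window (days 0-6 by
#' default, inclusive), recovery everything after.
#'
#' @param day numeric day(s).
#' @param treatment_window `c(first, last)` treatment days, inclusive.
#' @return character vector of phases.
#' @export
phase_of_day <- function(day, treatment_window = c(0, 6)) {
  ifelse(day < treatment_window[1], "pretreatment",
         ifelse(day <= treatment_window[2], "treatment", "recovery"))
}

# time profile of the perturbation: 0 before, 1 inside the window,
# exponentially decaying after at the group's recovery rate
perturbation_profile <- function(design, group) {
  days <- design$sampling_days
  w <- design$perturbation_window
  rate <- design$recovery_rate_by_group[[group]]
  prof <- numeric(length(days))
  prof[days >= w[1] & days <= w[2]] <- 1
  after <- days > w[2]
  prof[after] <- exp(-rate * (days[after] - w[2]))
  prof
}

#' Simulate longitudinal counts and sample metadata
#'
#' The generator inverts the analysis model: per animal, latent log
#' abundances follow a matrix-variate normal with row covariance
#' `latent_sd^2 * true_correlation` and column covariance a
#' squared-exponential kernel over the sampling days, so taxon-taxon
#' correlation and temporal smoothness are both planted. For treated groups
#' (ABX, ABXFT) the perturbation effect is subtracted from susceptible
#' (non-resistant) taxa inside the perturbation window and decays
#' exponentially afterwards at the group's recovery rate. ABXFT animals have
#' their latent state blended back toward their own day -4 state from the
#' transfaunation day onward. Counts are multinomial draws from the softmax
#' of the latent state at a uniformly drawn depth, making the observed data
#' compositional by construction.
#'
#' @param design a [simulation_design()].
#' @param truth a [synthetic_truth()] with matching `n_taxa`.
#' @param export_latent if `TRUE`, per-animal latent CLR trajectories
#'   (column-centered latent states) are returned for oracle checks.
#' @param seed seed; defaults to `design$seed`.
#' @return list of class `mb_simulation` with `counts` (taxa x samples
#'   integer matrix), `metadata` (data.frame: sample_id, animal_id, group,
#'   year, day, phase, depth), and optionally `latent_clr` (named list of
#'   taxa x day matrices).
#' @export
simulate_counts <- function(design, truth, export_latent = FALSE, seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"), inherits(truth, "synthetic_truth"))
  if (truth$n_taxa != design$n_taxa)
    stop("invalid truth: truth has ", truth$n_taxa, " taxa but design expects ", design$n_taxa)
  if (min_eigen(truth$true_correlation) < -1e-8)
    stop("invalid truth: true_correlation is not positive semi-definite")
  set_seed_if(seed)

  D <- design$n_taxa
  days <- design$sampling_days
  Tn <- length(days)
  ids <- taxon_ids(D)
  roster <- animal_roster(design)

  K <- se_kernel(days, truth$true_lengthscale, variance = 1, nugget = 1e-6)
  Lk <- chol(K)
  Sigma_row <- truth$latent_sd^2 * truth$true_correlation
  # planted correlation is PSD but may be singular; ridge for the factor only
  Ls <- chol(Sigma_row + diag(1e-8, D))

  # with the default spread some taxa hover at the rarefaction detection
  # limit, so presence profiles vary between samples even unperturbed
  base_mean <- stats::rnorm(D, 0, design$base_abundance_sd %||% 2)
  susceptible <- setdiff(truth$perturbed_taxa, truth$resistant_taxa)
  baseline_col <- which(days == -4)
  if (length(baseline_col) == 0)
    baseline_col <- if (any(days < 0)) max(which(days < 0)) else 1L

  counts <- matrix(0L, D, Tn * nrow(roster))
  meta <- vector("list", nrow(roster))
  latent <- if (export_latent) vector("list", nrow(roster)) else NULL

  col <- 0
  sample_names <- character(Tn * nrow(roster))
  for (a in seq_len(nrow(roster))) {
    animal <- roster$animal_id[a]
    group <- roster$group[a]
    Z <- matrix(stats::rnorm(D * Tn), D, Tn)
    X <- base_mean + stats::rnorm(D, 0, 0.3) + t(Ls) %*% Z %*% Lk
    if (group %in% c("ABX", "ABXFT") && length(susceptible) > 0) {
      prof <- perturbation_profile(design, group)
      pe <- rep_len(design$perturbation_effect, D)
      X[susceptible, ] <- X[susceptible, , drop = FALSE] -
        outer(pe[susceptible], prof)
    }
    if (group == "ABXFT") {
      post_ft <- which(days >= design$transfaunation_day)
      w <- design$ft_blend_weight
      for (t in post_ft) X[, t] <- w * X[, baseline_col] + (1 - w) * X[, t]
    }
    depth <- sample(design$depth_range[1]:design$depth_range[2], Tn, replace = TRUE)
    for (t in seq_len(Tn)) {
      p <- exp(X[, t] - max(X[, t]))
      p <- p / sum(p)
      col <- col + 1
      counts[, col] <- stats::rmultinom(1, depth[t], p)[, 1]
      sample_names[col] <- sprintf("%s_d%d", animal, days[t])
    }
    meta[[a]] <- data.frame(
      sample_id = sprintf("%s_d%d", animal, days),
      animal_id = animal, group = group, year = 1L, day = days,
      phase = phase_of_day(days, design$perturbation_window),
      depth = depth, stringsAsFactors = FALSE)
    if (export_latent) latent[[a]] <- sweep(X, 2, colMeans(X))
  }
  rownames(counts) <- ids
  colnames(counts) <- sample_names
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  out <- list(counts = counts, metadata = metadata,
              design = design, truth = truth)
  if (export_latent) {
    names(latent) <- roster$animal_id
    for (a in seq_along(latent)) {
      rownames(latent[[a]]) <- ids
      colnames(latent[[a]]) <- as.character(days)
    }
    out$latent_clr <- latent
  }
  class(out) <- "mb_simulation"
  out
}

abr_families <- c("Tetracycline", "Beta-lactam", "Aminoglycoside", "Macrolide",
                  "Vancomycin", "MDR", "Sulphonamide")

#' Simulate an antibiotic-resistance-gene (resistome) table
#'
#' Emits per-sample gene counts across the seven resistance-gene families
#' seen in lemur gut metagenomes, dominated by Tetracycline and Beta-lactam.
#' During the antibiotic window the Beta-lactam family of treated animals is
#' enriched by `treatment_enrichment` (decaying afterwards at the group's
#' recovery rate), and the overall ABR load of treated animals rises then
#' falls, giving the up-then-down longitudinal signature. Total sequenced
#' reads per sample are emitted alongside so ABR relative abundance is
#' computable.
#'
#' @param design a [simulation_design()].
#' @param n_genes number of distinct resistance genes (default 83).
#' @param base_family_props baseline family mixture; default close to the
#'   observed lemur means (Tetracycline ~51\%, Beta-lactam ~30\%, ...).
#' @param treatment_enrichment multiplicative Beta-lactam enrichment during
#'   treatment for ABX/ABXFT animals; 1 = null.
#' @param abr_load_enrichment multiplicative increase in overall ABR relative
#'   abundance during treatment for treated animals.
#' @param base_rel_abundance baseline ABR reads as a fraction of total reads.
#' @param total_reads_range per-sample total sequenced reads `c(min, max)`.
#' @param seed seed; defaults to `design$seed + 1000`.
#' @return list of class `resistome_table`: `genes` (gene x sample counts),
#'   `family_map` (data.frame gene, family), `totals` (named per-sample total
#'   reads), `metadata`.
#' @export
simulate_resistome <- function(design,
                               n_genes = 83,
                               base_family_props = c(Tetracycline = 0.514,
                                                     `Beta-lactam` = 0.295,
                                                     Aminoglycoside = 0.079,
                                                     Macrolide = 0.012,
                                                     Vancomycin = 0.05,
                                                     MDR = 0.03,
                                                     Sulphonamide = 0.02),
                               treatment_enrichment = 3,
                               abr_load_enrichment = 2,
                               base_rel_abundance = 1e-3,
                               total_reads_range = c(1e6, 3e6),
                               seed = design$seed + 1000L) {
  stopifnot(inherits(design, "simulation_design"), n_genes >= length(base_family_props))
  set_seed_if(seed)
  props <- base_family_props / sum(base_family_props)
  fams <- names(props)

  # allocate genes to families roughly proportionally, at least one each
  alloc <- pmax(1L, round(props * n_genes))
  while (sum(alloc) > n_genes) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < n_genes) alloc[which.max(props)] <- alloc[which.max(props)] + 1L
  family_map <- data.frame(
    gene = sprintf("gene_%03d", seq_len(n_genes)),
    family = rep(fams, times = alloc), stringsAsFactors = FALSE)
  gene_w <- stats::rgamma(n_genes, 1)  # within-family gene weights

  roster <- animal_roster(design)
  days <- design$sampling_days
  w <- design$perturbation_window
  meta <- list(); cols <- list(); totals <- numeric(0)
  for (a in seq_len(nrow(roster))) {
    group <- roster$group[a]
    treated <- group %in% c("ABX", "ABXFT")
    rate <- design$recovery_rate_by_group[[group]]
    for (day in days) {
      # enrichment factor: 1 pre-treatment, full during window, decaying after
      f <- 1
      if (treated && day >= w[1]) {
        f <- if (day <= w[2]) 1 else exp(-rate * (day - w[2]))
      } else f <- 0
      beta_f <- 1 + (treatment_enrichment - 1) * f
      load_f <- 1 + (abr_load_enrichment - 1) * f
      p_fam <- props
      p_fam["Beta-lactam"] <- p_fam["Beta-lactam"] * beta_f
      p_fam <- p_fam / sum(p_fam)
      fam_tot <- tapply(gene_w, family_map$family, sum)
      p_gene <- gene_w * p_fam[family_map$family] / fam_tot[family_map$family]
      p_gene <- p_gene / sum(p_gene)
      total <- round(stats::runif(1, total_reads_range[1], total_reads_range[2]))
      n_abr <- stats::rpois(1, total * base_rel_abundance * load_f)
      sid <- sprintf("%s_d%d", roster$animal_id[a], day)
      cols[[sid]] <- stats::rmultinom(1, n_abr, p_gene)[, 1]
      totals[sid] <- total
      meta[[sid]] <- data.frame(
        sample_id = sid, animal_id = roster$animal_id[a], group = group,
        year = 1L, day = day, phase = phase_of_day(day, w),
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(cbind, cols)
  rownames(genes) <- family_map$gene
  resistome_table(genes, family_map, totals,
                  metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))))
}
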