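#' Default pipeline configuration
#'
#' A single structured configuration covering every stage: simulation (or
#' input paths), filters, rarefaction, trajectory and association settings,
#' resistome options and the output directory. Serializes losslessly to
#' YAML via [write_run_config()] / [read_run_config()]. All randomness
#' derives from `seed` through fixed per-stage offsets.
#'
#' @param out_dir output directory.
#' @param seed root seed.
#' @param ... overrides of any default entry (nested lists are replaced
#'   wholesale).
#' @return named list of class `run_config`.
#' @export
run_config <- function(out_dir = "mbrecov_run", seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    simulate = list(enabled = TRUE, n_animals_per_group = c(CON = 2, ABX = 2, ABXFT = 2),
                    n_taxa = 40, depth_range = c(15000, 30000),
                    fraction_unassigned = 0.05),
    inputs = list(counts = NULL, metadata = NULL, taxonomy = NULL, tree = NULL),
    preprocess = list(min_reads = 10000, rarefy_depth = 15000,
                      min_samples = 5, min_total_frac = 1e-4),
    diversity = list(enabled = TRUE, shannon_base = 2, baseline_day = -4),
    trajectories = list(enabled = TRUE, n_perm = 199, n_knots = 8),
    association = list(
      enabled = TRUE, groups = c("ABX", "ABXFT"),
                       phases = list("all", "recovery"),
                       n_instances = 16, n_draws = 25,
                       lengthscale = 10, nugget = 0.1, strong_threshold = 0.5),
    resistome = list(enabled = TRUE, n_genes = 40, treatment_enrichment = 3),
    phase_window = c(0, 6))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Write / read a run configuration as YAML
#'
#' @param cfg a `run_config`.
#' @param path YAML file.
#' @return the config (read) or `path` invisibly (write).
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml drops names on scalars written from named vectors; restore shapes
  for (nm in c("n_animals_per_group"))
    if (!is.null(cfg$simulate[[nm]])) cfg$simulate[[nm]] <- unlist(cfg$simulate[[nm]])
  cfg$phase_window <- unlist(cfg$phase_window)
  cfg$preprocess <- lapply(cfg$preprocess, unlist)
  cfg$simulate$depth_range <- unlist(cfg$simulate$depth_range)
  class(cfg) <- c("run_config", "list")
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full perturbation-recovery pipeline
#'
#' Executes the enabled stages in order — simulate (or load inputs),
#' preprocess, diversity, trajectories, association, resistome — writing
#' each stage's artifacts into `cfg$out_dir` plus a JSON run report with a
#' config hash, per-stage record counts and timings. Fully deterministic
#' given `cfg$seed`.
#'
#' @param cfg a [run_config()].
#' @return the run report (named list), invisibly; written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config") || is.list(cfg))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  # hash the analysis settings, not the output location
  report <- list(config_hash = rlang::hash(unclass(cfg)[setdiff(names(cfg), "out_dir")]),
                 stages = list())
  seed <- cfg$seed
  note <- function(stage, status, ...) {
    report$stages[[stage]] <<- c(list(status = status), list(...))
  }

  # --- data: simulate or load ------------------------------------------
  if (isTRUE(cfg$simulate$enabled)) {
    design <- simulation_design(
      n_animals_per_group = cfg$simulate$n_animals_per_group,
      n_taxa = cfg$simulate$n_taxa,
      depth_range = cfg$simulate$depth_range,
      seed = seed)
    truth <- synthetic_truth(design$n_taxa, seed = seed + 1L)
    sim <- simulate_counts(design, truth, seed = seed + 2L)
    tt <- simulate_tree_and_taxonomy(design$n_taxa, seed = seed + 3L,
                                     fraction_unassigned = cfg$simulate$fraction_unassigned)
    counts <- sim$counts; metadata <- sim$metadata
    taxonomy <- tt$taxonomy; tree <- tt$tree
    write_count_table(counts, file.path(cfg$out_dir, "counts.tsv"))
    write_tsv(metadata, file.path(cfg$out_dir, "metadata.tsv"))
    write_tsv(taxonomy, file.path(cfg$out_dir, "taxonomy.tsv"))
    ape::write.tree(tree, file.path(cfg$out_dir, "tree.nwk"))
    note("simulate", "ok", n_taxa = nrow(counts), n_samples = ncol(counts))
  } else {
    counts <- read_count_table(cfg$inputs$counts)
    metadata <- read_sample_metadata(cfg$inputs$metadata, cfg$phase_window)
    taxonomy <- read_taxonomy(cfg$inputs$taxonomy)
    tree <- ape::read.tree(cfg$inputs$tree)
    note("load", "ok", n_taxa = nrow(counts), n_samples = ncol(counts))
  }

  # --- preprocess -------------------------------------------------------
  pp <- cfg$preprocess
  filtered <- filter_samples(counts, pp$min_reads)
  rarefied <- rarefy(filtered, pp$rarefy_depth, seed = seed + 10L)
  write_count_table(rarefied, file.path(cfg$out_dir, "rarefied.tsv"))
  note("preprocess", "ok", n_samples_in = ncol(counts),
       n_samples_rarefied = ncol(rarefied))

  # --- diversity --------------------------------------------------------
  baseline <- NULL
  if (isTRUE(cfg$diversity$enabled)) {
    H <- shannon(rarefied, cfg$diversity$shannon_base)
    write_tsv(data.frame(sample_id = names(H), shannon = as.numeric(H)),
              file.path(cfg$out_dir, "alpha_diversity.tsv"))
    dm <- unweighted_unifrac(rarefied, tree)
    write_distance_matrix(dm, file.path(cfg$out_dir, "unweighted_unifrac.tsv"))
    baseline <- suppressMessages(
      distance_from_baseline(dm, metadata, cfg$diversity$baseline_day))
    write_tsv(baseline, file.path(cfg$out_dir, "distance_from_baseline.tsv"))
    ord <- pcoa(dm, k = 2)
    write_tsv(data.frame(sample_id = rownames(ord$coordinates), ord$coordinates),
              file.path(cfg$out_dir, "pcoa.tsv"))
    md_pre <- metadata[metadata$phase == "pretreatment" &
                         metadata$sample_id %in% names(H), , drop = FALSE]
    kw <- kruskal_wallis_groups(H[md_pre$sample_id], md_pre$group)
    note("diversity", "ok", n_alpha = length(H), n_dm = nrow(dm),
         baseline_kw_H = kw$H, baseline_kw_p = kw$p)
  } else note("diversity", "skipped")

  # --- trajectories -----------------------------------------------------
  if (isTRUE(cfg$trajectories$enabled) && !is.null(baseline)) {
    series <- data.frame(day = baseline$day, value = baseline$distance,
                         animal = baseline$animal_id, group = baseline$group,
                         phase = baseline$phase)
    fit <- fit_group_smooths(series, n_knots = cfg$trajectories$n_knots)
    write_tsv(fit$grid, file.path(cfg$out_dir, "trajectory_grid.tsv"))
    cmp <- compare_groups_permutation(series, "CON", "ABX",
                                      n_perm = cfg$trajectories$n_perm,
                                      seed = seed + 20L,
                                      n_knots = cfg$trajectories$n_knots)
    jsonlite::write_json(list(statistic = cmp$statistic, p = cmp$p,
                              n_perm = cmp$n_perm),
                         file.path(cfg$out_dir, "trajectory_test.json"),
                         auto_unbox = TRUE, digits = NA)
    note("trajectories", "ok", n_obs = nrow(series),
         contrast_p = cmp$p)
  } else note("trajectories", "skipped")

  # --- association ------------------------------------------------------
  if (isTRUE(cfg$association$enabled)) {
    assoc_in <- prepare_association_input(counts, metadata, taxonomy,
                                          pp$min_samples, pp$min_total_frac)
    gcfg <- gp_config(lengthscale = cfg$association$lengthscale,
                      nugget = cfg$association$nugget,
                      n_instances = cfg$association$n_instances,
                      n_draws = cfg$association$n_draws)
    n_edges <- list()
    k <- 0
    for (grp in cfg$association$groups) for (ph in cfg$association$phases) {
      k <- k + 1
      phases <- if (identical(ph, "all")) c("treatment", "recovery") else ph
      res <- associate_group(assoc_in$table, assoc_in$metadata, grp,
                             phase = phases, config = gcfg,
                             strong_threshold = cfg$association$strong_threshold,
                             seed = seed + 30L + k)
      tag <- paste0(grp, "_", if (identical(ph, "all")) "all" else ph)
      write_edge_list(res$edges, file.path(cfg$out_dir, paste0("edges_", tag, ".tsv")))
      write_graphml(res$edges, file.path(cfg$out_dir, paste0("network_", tag, ".graphml")))
      n_edges[[tag]] <- sum(res$edges$strong)
    }
    note("association", "ok", strong_edges = n_edges,
         filter_log = assoc_in$log)
  } else note("association", "skipped")

  # --- resistome --------------------------------------------------------
  if (isTRUE(cfg$resistome$enabled) && isTRUE(cfg$simulate$enabled)) {
    design <- simulation_design(
      n_animals_per_group = cfg$simulate$n_animals_per_group,
      n_taxa = cfg$simulate$n_taxa,
      depth_range = cfg$simulate$depth_range, seed = seed)
    rt <- simulate_resistome(design, n_genes = cfg$resistome$n_genes,
                             treatment_enrichment = cfg$resistome$treatment_enrichment,
                             seed = seed + 40L)
    ls <- longitudinal_summary(rt)
    write_tsv(ls$overall, file.path(cfg$out_dir, "resistome_overall.tsv"))
    write_tsv(ls$by_family, file.path(cfg$out_dir, "resistome_by_family.tsv"))
    write_tsv(ls$trend, file.path(cfg$out_dir, "resistome_trend.tsv"))
    note("resistome", "ok", n_genes = nrow(rt$genes),
         n_samples = ncol(rt$genes))
  } else note("resistome", "skipped")

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}
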