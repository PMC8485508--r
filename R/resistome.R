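#' Construct a resistome (ABR gene) table
#'
#' Gene-by-sample non-negative integer counts plus a gene-to-family map over
#' the resistance-gene families {Tetracycline, Beta-lactam, Aminoglycoside,
#' Macrolide, Vancomycin, MDR, Sulphonamide, Other} and the per-sample total
#' sequenced reads needed for relative abundance. Families outside the named
#' set are mapped to "Other".
#'
#' @param genes gene x sample count matrix.
#' @param family_map data.frame with columns `gene`, `family`; every gene
#'   exactly once.
#' @param totals named per-sample total sequenced reads.
#' @param metadata optional sample metadata carried along.
#' @return object of class `resistome_table`.
#' @export
resistome_table <- function(genes, family_map, totals, metadata = NULL) {
  validate_count_table(genes)
  stopifnot(all(c("gene", "family") %in% names(family_map)))
  if (anyDuplicated(family_map$gene)) stop("a gene is mapped to more than one family")
  miss <- setdiff(rownames(genes), family_map$gene)
  if (length(miss) > 0) stop("genes without a family: ", paste(miss, collapse = ", "))
  known <- c(abr_families, "Other")
  family_map$family[!family_map$family %in% known] <- "Other"
  if (!all(colnames(genes) %in% names(totals)))
    stop("totals missing for sample(s): ",
         paste(setdiff(colnames(genes), names(totals)), collapse = ", "))
  totals <- totals[colnames(genes)]
  if (any(totals < colSums(genes)))
    stop("per-sample totals must be at least the summed gene counts")
  structure(list(genes = genes, family_map = family_map, totals = totals,
                 metadata = metadata),
            class = "resistome_table")
}

#' Per-sample resistance-gene family proportions
#'
#' Fractions over families summing to 1 per sample; a sample with zero ABR
#' reads yields an all-zero column with a warning (never NaN).
#'
#' @param rt a [resistome_table()].
#' @return family x sample matrix of fractions.
#' @export
family_proportions <- function(rt) {
  stopifnot(inherits(rt, "resistome_table"))
  fam <- rt$family_map$family[match(rownames(rt$genes), rt$family_map$gene)]
  byfam <- rowsum(rt$genes, group = fam)
  tot <- colSums(byfam)
  zero <- tot == 0
  if (any(zero)) {
    warning("sample(s) with zero ABR reads: ",
            paste(colnames(rt$genes)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  sweep(byfam, 2, tot, "/")
}

#' Per-sample ABR relative abundance
#'
#' Summed resistance-gene counts divided by total sequenced reads.
#'
#' @param rt a [resistome_table()].
#' @return named numeric vector.
#' @export
abr_relative_abundance <- function(rt) {
  stopifnot(inherits(rt, "resistome_table"))
  colSums(rt$genes) / rt$totals
}

classify_trend <- function(pre, treat, recov) {
  if (any(is.na(c(pre, treat, recov)))) return(NA_character_)
  up1 <- treat > pre; up2 <- recov > treat
  if (up1 && !up2) "up-then-down"
  else if (up1 && up2) "up-then-up"
  else if (!up1 && up2) "down-then-up"
  else "down-then-down"
}

#' Longitudinal group x day resistome summary
#'
#' Per (group, day): mean and SEM (over animals) of ABR relative abundance,
#' and of each family's proportion. Cells with a single animal report SEM
#' as `NA`. Also classifies each group's pre -> treatment -> recovery trend
#' in mean ABR relative abundance (the up-then-down signature of treated
#' animals).
#'
#' @param rt a [resistome_table()].
#' @param metadata data.frame with `sample_id`, `animal_id`, `group`, `day`,
#'   `phase`; defaults to the metadata bundled with `rt`.
#' @return list with `overall` (group, day, phase, n, mean, sem),
#'   `by_family` (adds `family`), `trend` (group, trend).
#' @export
longitudinal_summary <- function(rt, metadata = rt$metadata) {
  stopifnot(inherits(rt, "resistome_table"), !is.null(metadata))
  md <- metadata[match(colnames(rt$genes), metadata$sample_id), , drop = FALSE]
  rel <- abr_relative_abundance(rt)
  props <- suppressWarnings(family_proportions(rt))
  sem <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
  cell <- function(values, g, d) {
    v <- values[md$group == g & md$day == d]
    c(n = length(v), mean = mean(v), sem = sem(v))
  }
  cells <- unique(md[, c("group", "day", "phase")])
  cells <- cells[order(cells$group, cells$day), , drop = FALSE]
  overall <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    s <- cell(rel, cells$group[i], cells$day[i])
    data.frame(cells[i, , drop = FALSE], n = s["n"], mean = s["mean"], sem = s["sem"])
  }))
  by_family <- do.call(rbind, lapply(rownames(props), function(f) {
    do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      s <- cell(props[f, ], cells$group[i], cells$day[i])
      data.frame(cells[i, , drop = FALSE], family = f,
                 n = s["n"], mean = s["mean"], sem = s["sem"])
    }))
  }))
  trend <- do.call(rbind, lapply(unique(md$group), function(g) {
    pm <- function(ph) {
      v <- rel[md$group == g & md$phase == ph]
      if (length(v) == 0) NA_real_ else mean(v)
    }
    data.frame(group = g,
               trend = classify_trend(pm("pretreatment"), pm("treatment"), pm("recovery")),
               stringsAsFactors = FALSE)
  }))
  rownames(overall) <- rownames(by_family) <- rownames(trend) <- NULL
  list(overall = overall, by_family = by_family, trend = trend)
}

#' Cross-sectional ABR versus lifetime antibiotic exposure
#'
#' Per-animal ABR relative abundance next to that animal's lifetime count
#' of antibiotic courses, ordered by exposure, plus the Spearman rank
#' correlation between the two with a permutation p-value. With constant
#' exposure the correlation is undefined and reported as `NA`. The
#' correlation test is a quantitative aid to what is otherwise a
#' qualitative comparison at these sample sizes.
#'
#' @param rt a [resistome_table()] with one sample per animal (if several,
#'   per-animal means are used).
#' @param exposure named numeric vector: lifetime antibiotic courses per
#'   animal; must cover every animal in the table.
#' @param n_perm permutations for the p-value (default 999).
#' @param seed integer seed.
#' @return list with `per_animal` (animal, exposure, abr_relative_abundance,
#'   ordered by exposure), `spearman_rho`, `p`.
#' @export
cross_sectional_summary <- function(rt, exposure, n_perm = 999, seed = NULL) {
  stopifnot(inherits(rt, "resistome_table"))
  md <- rt$metadata
  if (is.null(md)) stop("resistome table carries no metadata to map samples to animals")
  md <- md[match(colnames(rt$genes), md$sample_id), , drop = FALSE]
  miss <- setdiff(unique(md$animal_id), names(exposure))
  if (length(miss) > 0) stop("exposure unknown for animal(s): ", paste(miss, collapse = ", "))
  rel <- abr_relative_abundance(rt)
  per <- tapply(rel, md$animal_id, mean)
  tab <- data.frame(animal = names(per), exposure = exposure[names(per)],
                    abr_relative_abundance = as.numeric(per),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$exposure), , drop = FALSE]
  rownames(tab) <- NULL
  if (length(unique(tab$exposure)) < 2)
    return(list(per_animal = tab, spearman_rho = NA_real_, p = NA_real_))
  set_seed_if(seed)
  rho <- stats::cor(tab$exposure, tab$abr_relative_abundance, method = "spearman")
  perm <- replicate(n_perm, abs(stats::cor(sample(tab$exposure),
                                           tab$abr_relative_abundance,
                                           method = "spearman")))
  p <- (1 + sum(perm >= abs(rho))) / (1 + n_perm)
  list(per_animal = tab, spearman_rho = rho, p = p)
}
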