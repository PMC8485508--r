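#' Drop shallow samples from a count table
#'
#' Retains exactly the samples whose column sum is at least `min_reads`
#' (boundary inclusive: a sample with exactly `min_reads` reads is kept).
#'
#' @param table taxa x samples count matrix.
#' @param min_reads minimum per-sample read depth (default 10000).
#' @return the filtered count table; the taxon set is unchanged.
#' @export
filter_samples <- function(table, min_reads = 10000) {
  validate_count_table(table)
  stopifnot(min_reads >= 0)
  keep <- colSums(table) >= min_reads
  out <- table[, keep, drop = FALSE]
  if (ncol(out) == 0) warning("all samples removed by the read-depth filter")
  out
}

#' Rarefy samples to a common depth
#'
#' Uniform without-replacement subsampling (hypergeometric) of each sample's
#' reads down to `depth`; samples with fewer reads than `depth` are dropped.
#' Without-replacement semantics match the QIIME2 subsampling the presence
#' profiles downstream rely on.
#'
#' @param table taxa x samples count matrix.
#' @param depth target reads per sample (default 15000).
#' @param seed integer seed.
#' @return count table whose columns each sum exactly to `depth`.
#' @export
rarefy <- function(table, depth = 15000, seed = NULL) {
  validate_count_table(table)
  stopifnot(depth >= 1)
  set_seed_if(seed)
  keep <- colSums(table) >= depth
  out <- table[, keep, drop = FALSE]
  if (ncol(out) == 0) {
    warning("no samples have at least ", depth, " reads")
    return(out)
  }
  # vegan's advisory about large smallest counts is irrelevant here: the
  # input is validated as integer counts
  sub <- withCallingHandlers(
    t(vegan::rrarefy(t(out), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  storage.mode(sub) <- "integer"
  dimnames(sub) <- dimnames(out)
  sub
}

# split "k__Bacteria; p__X; ...; g__Y; s__Z" into trimmed rank labels
parse_lineage <- function(lineage) {
  lapply(strsplit(lineage, ";", fixed = TRUE), function(x) {
    x <- trimws(x)
    x[nzchar(x)]
  })
}

#' Collapse features to the genus level
#'
#' Features sharing a genus label are summed. Features whose lineage does not
#' resolve to genus (empty or missing `g__` field) are collapsed under their
#' deepest resolved rank, labelled `"<rank label> (unresolved)"`. Total
#' counts are conserved exactly.
#'
#' @param table taxa x samples count matrix, rows named by feature id.
#' @param taxonomy data.frame with columns `feature_id` and `lineage`
#'   (semicolon-delimited `k__...;p__...;...` QIIME2 dialect).
#' @return genus-level count table.
#' @export
collapse_genus <- function(table, taxonomy) {
  validate_count_table(table)
  stopifnot(all(c("feature_id", "lineage") %in% names(taxonomy)))
  miss <- setdiff(rownames(table), taxonomy$feature_id)
  if (length(miss) > 0)
    stop("features without a lineage entry: ", paste(miss, collapse = ", "))
  lin <- parse_lineage(taxonomy$lineage[match(rownames(table), taxonomy$feature_id)])
  label <- vapply(lin, function(ranks) {
    g <- grep("^g__.+", ranks, value = TRUE)
    if (length(g) > 0 && nchar(sub("^g__", "", g[1])) > 0) g[1]
    else paste0(ranks[length(ranks)], " (unresolved)")
  }, character(1))
  out <- rowsum(table, group = label)
  storage.mode(out) <- "integer"
  out[order(rownames(out)), , drop = FALSE]
}

#' Drop rare taxa by prevalence
#'
#' Removes taxa with nonzero counts in fewer than `min_samples` samples
#' across the full table (a taxon present in exactly `min_samples` samples
#' is retained).
#'
#' @param table taxa x samples count matrix.
#' @param min_samples prevalence threshold (default 5).
#' @return filtered count table.
#' @export
filter_rare_taxa <- function(table, min_samples = 5) {
  validate_count_table(table)
  stopifnot(min_samples >= 0)
  table[rowSums(table > 0) >= min_samples, , drop = FALSE]
}

#' Fold low-abundance taxa into an "Other" row
#'
#' Taxa whose share of the grand total is strictly below `min_total_frac`
#' are summed into a single `"Other"` row; totals are conserved. The
#' fraction of counts moved is attached as attribute `fraction_other` and
#' reported via `message()`.
#'
#' @param table taxa x samples count matrix.
#' @param min_total_frac fraction-of-total threshold (default 1e-4, i.e.
#'   0.01\%).
#' @return count table with at most one added "Other" row.
#' @export
group_other_taxa <- function(table, min_total_frac = 1e-4) {
  validate_count_table(table)
  stopifnot(min_total_frac >= 0, min_total_frac < 1)
  grand <- sum(table)
  share <- rowSums(table) / max(grand, 1)
  fold <- share < min_total_frac
  moved <- sum(table[fold, , drop = FALSE]) / max(grand, 1)
  if (!any(fold)) {
    attr(table, "fraction_other") <- 0
    return(table)
  }
  other <- colSums(table[fold, , drop = FALSE])
  out <- rbind(table[!fold, , drop = FALSE], Other = other)
  storage.mode(out) <- "integer"
  message(sprintf("folded %d taxa (%.3f%% of counts) into 'Other'",
                  sum(fold), 100 * moved))
  attr(out, "fraction_other") <- moved
  out
}

#' Centered log-ratio transform
#'
#' `clr(x)_j = log(x_j) - mean(log(x))`: each composition is mapped to a
#' zero-sum real vector, where covariance between taxa is meaningful.
#' Inputs must be strictly positive; zeros are expected to be handled
#' upstream by Dirichlet resampling.
#'
#' @param x positive numeric vector, or matrix with one composition per
#'   column.
#' @return same shape as `x`; every composition sums to zero.
#' @export
clr_transform <- function(x) {
  if (any(x <= 0)) stop("clr_transform requires strictly positive values; resample zeros upstream")
  lx <- log(x)
  if (is.matrix(x)) sweep(lx, 2, colMeans(lx)) else lx - mean(lx)
}

#' Dirichlet Monte-Carlo CLR instances for one animal's series
#'
#' Propagates sequencing-count uncertainty the ALDEx2 way: for each instance
#' and each timepoint, a composition is drawn from
#' `Dirichlet(counts + prior)` and CLR-transformed. The result is a list of
#' plausible real-valued taxa x timepoint matrices ("instances") on which the
#' Gaussian-process covariation engine operates.
#'
#' @param series taxa x timepoints count matrix for one animal, columns in
#'   day order.
#' @param days numeric days matching the columns; defaults to `1:T`.
#' @param n_instances number of Monte-Carlo instances (default 128).
#' @param prior Dirichlet concentration added to every cell (default 0.5).
#' @param animal_id optional label carried in each instance.
#' @param seed integer seed.
#' @return list of `clr_instance` objects, each with fields `values`
#'   (taxa x timepoints, columns sum to 0), `instance_index`, `animal_id`,
#'   `days`.
#' @export
dirichlet_instances <- function(series, days = NULL, n_instances = 128,
                                prior = 0.5, animal_id = NULL, seed = NULL) {
  if (length(series) == 0 || is.null(dim(series)) || ncol(series) == 0)
    stop("empty series: need at least one timepoint of counts")
  stopifnot(n_instances >= 1, prior > 0)
  days <- days %||% seq_len(ncol(series))
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  stopifnot(length(days) == ncol(series))
  set_seed_if(seed)
  D <- nrow(series); Tn <- ncol(series)
  lapply(seq_len(n_instances), function(i) {
    g <- matrix(stats::rgamma(D * Tn, shape = series + prior), D, Tn,
                dimnames = dimnames(series))
    p <- sweep(g, 2, colSums(g), "/")
    structure(list(values = clr_transform(p), instance_index = i,
                   animal_id = animal_id, days = days),
              class = "clr_instance")
  })
}

#' The association-analysis preprocessing chain
#'
#' Applies, in order: drop pretreatment samples, drop rare taxa (prevalence
#' < `min_samples`), collapse to genus, fold genera below `min_total_frac`
#' of total counts into "Other". Records counts removed at each step.
#'
#' @param table taxa x samples count matrix (raw, unrarefied counts).
#' @param metadata sample metadata with `sample_id` and `phase`.
#' @param taxonomy lineage table for [collapse_genus()].
#' @param min_samples prevalence threshold.
#' @param min_total_frac "Other" threshold.
#' @return list with `table` (filtered genus-level counts), `metadata`
#'   (matching rows), and `log` (data.frame of per-step taxon/sample/count
#'   tallies).
#' @export
prepare_association_input <- function(table, metadata, taxonomy,
                                      min_samples = 5, min_total_frac = 1e-4) {
  validate_count_table(table)
  stopifnot(all(colnames(table) %in% metadata$sample_id))
  steps <- list()
  tally <- function(tab, step) data.frame(step = step, n_taxa = nrow(tab),
                                          n_samples = ncol(tab), total = sum(tab))
  steps[[1]] <- tally(table, "input")
  keep <- metadata$sample_id[metadata$phase != "pretreatment"]
  table <- table[, colnames(table) %in% keep, drop = FALSE]
  steps[[2]] <- tally(table, "drop_pretreatment")
  table <- filter_rare_taxa(table, min_samples)
  steps[[3]] <- tally(table, "filter_rare_taxa")
  table <- collapse_genus(table, taxonomy)
  steps[[4]] <- tally(table, "collapse_genus")
  table <- suppressMessages(group_other_taxa(table, min_total_frac))
  steps[[5]] <- tally(table, "group_other_taxa")
  list(table = table,
       metadata = metadata[metadata$sample_id %in% colnames(table), , drop = FALSE],
       log = do.call(rbind, steps))
}
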