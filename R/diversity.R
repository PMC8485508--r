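#' Shannon-Weaver alpha diversity
#'
#' `H = -sum(p_i * log(p_i, base))` over taxa with nonzero counts. Base 2
#' (bits) by default, matching common amplicon-pipeline output; natural log
#' is available via `log_base = exp(1)`. The base used is attached as
#' attribute `log_base`.
#'
#' @param table taxa x samples count matrix.
#' @param log_base logarithm base (default 2).
#' @return named numeric vector, one value per sample.
#' @export
shannon <- function(table, log_base = 2) {
  validate_count_table(table)
  tot <- colSums(table)
  if (any(tot == 0)) stop("empty sample(s): ", paste(colnames(table)[tot == 0], collapse = ", "))
  H <- apply(table, 2, function(x) {
    p <- x[x > 0] / sum(x)
    -sum(p * log(p, base = log_base))
  })
  attr(H, "log_base") <- log_base
  H
}

# edge x sample presence matrix: an edge is "present" in a sample if any
# descendant leaf has count > 0; computed by one postorder accumulation
edge_presence <- function(table, tree) {
  miss <- setdiff(rownames(table), tree$tip.label)
  if (length(miss) > 0)
    stop("taxa absent from the tree: ", paste(miss, collapse = ", "))
  tr <- stats::reorder(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  pres <- matrix(FALSE, n_node, ncol(table))
  idx <- match(tr$tip.label, rownames(table))
  have <- !is.na(idx)
  pres[seq_len(n_tip)[have], ] <- table[idx[have], , drop = FALSE] > 0
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
    pres[p, ] <- pres[p, ] | pres[ch, ]
  }
  list(E = pres[tr$edge[, 2], , drop = FALSE] * 1, bl = tr$edge.length)
}

#' Unweighted UniFrac distance matrix
#'
#' Presence-based phylogenetic beta diversity: for two samples, the branch
#' length leading exclusively to leaves present in one sample, divided by
#' the branch length leading to leaves present in either. A branch belongs
#' to a sample when any descendant leaf has count > 0, so the metric weights
#' rare and abundant taxa equally. Comparable presence profiles assume the
#' table was rarefied to a common depth first.
#'
#' @param table taxa x samples count matrix; every nonzero taxon must be a
#'   leaf of `tree`.
#' @param tree rooted [ape::phylo] with branch lengths >= 0.
#' @return symmetric samples x samples matrix with zero diagonal, values in
#'   `[0, 1]`.
#' @export
unweighted_unifrac <- function(table, tree) {
  validate_count_table(table)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  ep <- edge_presence(table, tree)
  wE <- ep$bl * ep$E
  shared <- crossprod(ep$E, wE)              # sum of bl over branches in both
  tot <- colSums(wE)                         # branch length spanned by each
  n <- ncol(table)
  union <- outer(tot, tot, "+") - shared
  uniq <- outer(tot, tot, "+") - 2 * shared
  d <- ifelse(union > 0, uniq / union, 0)
  diag(d) <- 0
  dimnames(d) <- list(colnames(table), colnames(table))
  d
}

#' Weighted (normalized) UniFrac distance matrix
#'
#' Abundance-weighted companion metric: branch lengths weighted by the
#' absolute difference of the relative abundances descending through each
#' branch, normalized by the weighted total so values lie in `[0, 1]`.
#'
#' @inheritParams unweighted_unifrac
#' @return symmetric samples x samples matrix.
#' @export
weighted_unifrac <- function(table, tree) {
  validate_count_table(table)
  miss <- setdiff(rownames(table), tree$tip.label)
  if (length(miss) > 0)
    stop("taxa absent from the tree: ", paste(miss, collapse = ", "))
  tr <- stats::reorder(tree, "postorder")
  n_tip <- length(tr$tip.label)
  rel <- sweep(table, 2, colSums(table), "/")
  prop <- matrix(0, n_tip + tr$Nnode, ncol(table))
  idx <- match(tr$tip.label, rownames(table))
  have <- !is.na(idx)
  prop[seq_len(n_tip)[have], ] <- rel[idx[have], , drop = FALSE]
  for (i in seq_len(nrow(tr$edge)))
    prop[tr$edge[i, 1], ] <- prop[tr$edge[i, 1], ] + prop[tr$edge[i, 2], ]
  P <- prop[tr$edge[, 2], , drop = FALSE]
  bl <- tr$edge.length
  n <- ncol(table)
  d <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    num <- sum(bl * abs(P[, a] - P[, b]))
    den <- sum(bl * (P[, a] + P[, b]))
    d[a, b] <- d[b, a] <- if (den > 0) num / den else 0
  }
  d
}

#' Distance of every sample from its animal's baseline community
#'
#' Each animal's baseline is its sample at `baseline_day` (default day -4,
#' the sample used for fecal transfaunation); if that day is missing the
#' nearest pretreatment sample is used and a message emitted. Animals with
#' no pretreatment sample are excluded with a warning.
#'
#' @param dm samples x samples distance matrix.
#' @param metadata data.frame with `sample_id`, `animal_id`, `group`, `day`,
#'   `phase`.
#' @param baseline_day designated baseline day.
#' @return data.frame (one row per sample of retained animals):
#'   `sample_id`, `animal_id`, `group`, `day`, `phase`, `distance`,
#'   `baseline_sample`.
#' @export
distance_from_baseline <- function(dm, metadata, baseline_day = -4) {
  stopifnot(all(rownames(dm) == colnames(dm)))
  md <- metadata[metadata$sample_id %in% rownames(dm), , drop = FALSE]
  out <- list()
  for (animal in unique(md$animal_id)) {
    rows <- md[md$animal_id == animal, , drop = FALSE]
    pre <- rows[rows$day < 0, , drop = FALSE]
    if (nrow(pre) == 0) {
      warning("animal ", animal, " has no pretreatment sample; excluded")
      next
    }
    base_row <- pre[pre$day == baseline_day, , drop = FALSE]
    if (nrow(base_row) == 0) {
      base_row <- pre[which.min(abs(pre$day - baseline_day)), , drop = FALSE]
      message("animal ", animal, ": no day ", baseline_day,
              " sample; using day ", base_row$day, " as baseline")
    }
    base_id <- base_row$sample_id[1]
    out[[animal]] <- data.frame(
      sample_id = rows$sample_id, animal_id = animal, group = rows$group,
      day = rows$day, phase = rows$phase,
      distance = dm[rows$sample_id, base_id],
      baseline_sample = base_id, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Principal Coordinates Analysis (classical MDS)
#'
#' Double-centering of `-0.5 * D^2` followed by eigendecomposition; the top
#' `k` positive components are returned. If fewer than `k` positive
#' eigenvalues exist the available components are returned with a warning.
#'
#' @param dm symmetric distance matrix.
#' @param k number of coordinate axes requested (default 2).
#' @return list with `coordinates` (samples x k'), `eigenvalues` (all), and
#'   `proportion_explained` over positive eigenvalues.
#' @export
pcoa <- function(dm, k = 2) {
  n <- nrow(as.matrix(dm))
  if (k > n - 1) {
    warning("requested ", k, " components but only ", n - 1,
            " are available; returning fewer components")
    k <- n - 1
  }
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = k, eig = TRUE))
  got <- ncol(fit$points)
  if (got < k) warning("only ", got, " positive components available (requested ", k, ")")
  pos <- fit$eig[fit$eig > 0]
  list(coordinates = fit$points,
       eigenvalues = fit$eig,
       proportion_explained = pos / sum(pos))
}

#' Kruskal-Wallis rank test across experimental groups
#'
#' Tie-corrected H statistic with a chi-square p-value on `g - 1` degrees of
#' freedom; used for the baseline between-group comparison.
#'
#' @param values per-sample numeric values (e.g. alpha diversity).
#' @param groups group labels of the same length.
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis_groups <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("every group must contain samples")
  if (length(unique(values)) == 1)  # fully tied: H degenerates to 0
    return(list(H = 0, p = 1, df = nlevels(groups) - 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}
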