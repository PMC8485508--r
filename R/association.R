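#' Configuration for the Gaussian-process covariation engine
#'
#' The engine models one animal's CLR matrix `Y` (D taxa x T timepoints,
#' observed at days `t`) as matrix-normal with row covariance `Sigma`
#' (the taxon-taxon covariance of interest, inverse-Wishart prior) and
#' column covariance a squared-exponential kernel over the sampling days,
#' which absorbs the irregular temporal spacing and autocorrelation of the
#' series.
#'
#' Only the product of row and column covariances is identifiable in a
#' matrix-normal model, so the kernel's marginal variance acts purely as the
#' weight of the unit prior scale `Xi = I` relative to the whitened
#' evidence: the default 0.05 keeps the prior about two orders of magnitude
#' below the evidence from a unit-variance CLR series, i.e. weakly
#' informative in practice and not just in name.
#'
#' @param lengthscale kernel bandwidth in days (default 10, spanning the
#'   dense 2-day and sparse weekly-monthly sampling).
#' @param variance kernel marginal variance (default 0.05; see above).
#' @param nugget observation-noise variance added to the kernel diagonal;
#'   must be > 0 when days repeat.
#' @param prior_dof inverse-Wishart degrees of freedom `nu`; default
#'   `D + 3` (weakly informative with a proper mean), resolved at fit time.
#' @param prior_scale inverse-Wishart scale matrix `Xi`; default identity,
#'   resolved at fit time.
#' @param n_instances Dirichlet Monte-Carlo instances per animal.
#' @param n_draws posterior covariance draws per instance.
#' @param seed integer seed for the posterior sampling.
#' @return object of class `gp_config`.
#' @export
gp_config <- function(lengthscale = 10, variance = 0.05, nugget = 0.1,
                      prior_dof = NULL, prior_scale = NULL,
                      n_instances = 128, n_draws = 50, seed = NULL) {
  stopifnot(lengthscale > 0, variance > 0, nugget >= 0,
            n_instances >= 1, n_draws >= 1)
  structure(list(lengthscale = lengthscale, variance = variance,
                 nugget = nugget, prior_dof = prior_dof,
                 prior_scale = prior_scale, n_instances = n_instances,
                 n_draws = n_draws, seed = seed),
            class = "gp_config")
}

# one inverse-Wishart posterior: draws n covariance (or correlation)
# matrices from IW(df, S) via Wishart draws on the inverted scale
riw_draws <- function(n, df, S, correlation = TRUE) {
  Sinv <- chol2inv(chol(S))
  W <- stats::rWishart(n, df, Sinv)
  lapply(seq_len(n), function(i) {
    Sig <- chol2inv(chol(W[, , i]))
    if (correlation) stats::cov2cor(Sig) else Sig
  })
}

#' Posterior distribution of taxon-taxon correlations
#'
#' For every CLR instance (per animal, per Dirichlet draw): builds the
#' temporal Gram matrix `K` at that instance's days, centers each taxon at
#' its row mean, forms `SSE = Yc K^-1 Yc'`, and draws from the conjugate
#' matrix-normal/inverse-Wishart posterior
#' `Sigma | Y ~ IW(nu + T, Xi + SSE)`. Every covariance draw is converted to
#' a correlation matrix and the draws are pooled across instances and
#' animals, approximating a group-level posterior over biological
#' replicates.
#'
#' @param instances list of `clr_instance` objects (from
#'   [dirichlet_instances()]), possibly spanning several animals of one
#'   group/phase; all must share the taxon set and have >= 3 timepoints.
#' @param config a [gp_config()].
#' @param provenance optional named list (group, phase, ...) stored with the
#'   posterior.
#' @param correlation convert every covariance draw to a correlation matrix
#'   (default); `FALSE` keeps raw covariance draws, e.g. for checking the
#'   conjugate posterior mean against its closed form.
#' @return object of class `gp_posterior`: `draws` (D x D x n_total array of
#'   correlation matrices), `taxon_ids`, `config`, `provenance`.
#' @export
fit_gp_posterior <- function(instances, config = gp_config(), provenance = list(),
                             correlation = TRUE) {
  stopifnot(length(instances) >= 1, inherits(config, "gp_config"))
  Y1 <- instances[[1]]$values
  D <- nrow(Y1)
  ids <- rownames(Y1) %||% taxon_ids(D)
  for (ins in instances) {
    if (nrow(ins$values) != D) stop("all instances must share the taxon set")
    if (ncol(ins$values) < 3) stop("each instance needs at least 3 timepoints")
  }
  nu <- config$prior_dof %||% (D + 3)
  if (nu <= D + 1) stop("prior_dof must exceed n_taxa + 1 for a proper prior mean")
  Xi <- config$prior_scale %||% diag(D)
  if (min_eigen(Xi) < -1e-10) stop("prior_scale must be positive semi-definite")
  set_seed_if(config$seed)

  # instances from the same animal share days; cache K^-1 by day signature
  kinv_cache <- new.env(parent = emptyenv())
  kinv_for <- function(days) {
    key <- paste(days, collapse = ",")
    if (!is.null(kinv_cache[[key]])) return(kinv_cache[[key]])
    K <- se_kernel(days, config$lengthscale, config$variance, config$nugget)
    ch <- tryCatch(chol(K), error = function(e)
      stop("temporal kernel not positive-definite (duplicate days?); set nugget > 0"))
    kinv_cache[[key]] <- chol2inv(ch)
    kinv_cache[[key]]
  }

  draws <- vector("list", length(instances))
  for (i in seq_along(instances)) {
    ins <- instances[[i]]
    Kinv <- kinv_for(ins$days)
    Yc <- ins$values - rowMeans(ins$values)
    SSE <- Yc %*% Kinv %*% t(Yc)
    Tn <- ncol(ins$values)
    draws[[i]] <- riw_draws(config$n_draws, nu + Tn, Xi + SSE, correlation)
  }
  draws <- unlist(draws, recursive = FALSE)
  arr <- array(unlist(draws), dim = c(D, D, length(draws)),
               dimnames = list(ids, ids, NULL))
  structure(list(draws = arr, taxon_ids = ids, config = config,
                 provenance = provenance),
            class = "gp_posterior")
}

#' Summarize a correlation posterior into association edges
#'
#' One edge per unordered taxon pair with the posterior median and 95\%
#' equal-tailed credible interval over the pooled draws. An edge is
#' `significant` when the credible interval excludes zero, and `strong`
#' when the absolute median exceeds `strong_threshold` (strictly); the two
#' flags are independent. Output is sorted by absolute median, descending.
#'
#' @param post a `gp_posterior`.
#' @param strong_threshold strong-association cutoff on `|median rho|`
#'   (default 0.5).
#' @param level credible level (default 0.95).
#' @return data.frame of class `association_edges`: `taxon_i`, `taxon_j`,
#'   `rho_median`, `ci_low`, `ci_high`, `significant`, `strong`, `sign`.
#' @export
summarize_associations <- function(post, strong_threshold = 0.5, level = 0.95) {
  stopifnot(inherits(post, "gp_posterior"))
  n_draws <- dim(post$draws)[3]
  if (n_draws < 2) stop("need at least 2 pooled draws")
  D <- dim(post$draws)[1]
  ut <- which(upper.tri(diag(D)), arr.ind = TRUE)
  flat <- matrix(post$draws, D * D, n_draws)
  rows <- (ut[, 2] - 1) * D + ut[, 1]
  vals <- flat[rows, , drop = FALSE]          # pairs x draws
  alpha <- (1 - level) / 2
  qs <- apply(vals, 1, stats::quantile, probs = c(alpha, 0.5, 1 - alpha), names = FALSE)
  out <- data.frame(
    taxon_i = post$taxon_ids[ut[, 1]],
    taxon_j = post$taxon_ids[ut[, 2]],
    rho_median = qs[2, ], ci_low = qs[1, ], ci_high = qs[3, ],
    stringsAsFactors = FALSE)
  out$significant <- out$ci_low > 0 | out$ci_high < 0
  out$strong <- abs(out$rho_median) > strong_threshold
  out$sign <- sign(out$rho_median)
  out <- out[order(-abs(out$rho_median)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("association_edges", "data.frame")
  out
}

#' Compare two strong-association networks
#'
#' Reports edges strong in both lists, edges strong in exactly one, and
#' sign agreement among the shared edges, with counts by sign.
#'
#' @param edges_a,edges_b edge tables from [summarize_associations()].
#' @param strong_only compare strong edges only (default) or all edges.
#' @return list with `shared` (data.frame: pair, sign in each, flip flag),
#'   `unique_a`, `unique_b`, and `counts` (named totals incl. positives /
#'   negatives per side and sign flips).
#' @export
compare_networks <- function(edges_a, edges_b, strong_only = TRUE) {
  pick <- function(e) if (strong_only) e[e$strong, , drop = FALSE] else e
  a <- pick(edges_a); b <- pick(edges_b)
  a$key <- pair_key(a$taxon_i, a$taxon_j)
  b$key <- pair_key(b$taxon_i, b$taxon_j)
  shared_keys <- intersect(a$key, b$key)
  shared <- data.frame(
    pair = shared_keys,
    sign_a = a$sign[match(shared_keys, a$key)],
    sign_b = b$sign[match(shared_keys, b$key)],
    stringsAsFactors = FALSE)
  shared$sign_flip <- shared$sign_a != shared$sign_b
  counts <- c(
    n_a = nrow(a), n_b = nrow(b),
    n_a_positive = sum(a$sign > 0), n_a_negative = sum(a$sign < 0),
    n_b_positive = sum(b$sign > 0), n_b_negative = sum(b$sign < 0),
    n_shared = length(shared_keys),
    n_shared_positive = sum(shared$sign_a > 0 & !shared$sign_flip),
    n_shared_negative = sum(shared$sign_a < 0 & !shared$sign_flip),
    n_sign_flips = sum(shared$sign_flip),
    n_unique_a = sum(!a$key %in% shared_keys),
    n_unique_b = sum(!b$key %in% shared_keys))
  list(shared = shared,
       unique_a = a[!a$key %in% shared_keys, setdiff(names(a), "key"), drop = FALSE],
       unique_b = b[!b$key %in% shared_keys, setdiff(names(b), "key"), drop = FALSE],
       counts = counts)
}

#' Posterior CLR trajectory of one taxon
#'
#' Per observed day, percentiles (2.5, 25, 50, 75, 97.5) of the taxon's CLR
#' value across Dirichlet instances (pooled over however many animals the
#' instances span). A rising treatment-phase median while other taxa crash
#' is the antibiotic-resistance signature of taxa such as *Bacteroides*.
#'
#' @param instances list of `clr_instance` objects.
#' @param taxon taxon id (row name) or index.
#' @return data.frame: `day`, `q2.5`, `q25`, `median`, `q75`, `q97.5`, `n`.
#' @export
log_ratio_trajectory <- function(instances, taxon) {
  stopifnot(length(instances) >= 1)
  vals <- list()
  for (ins in instances) {
    ids <- rownames(ins$values)
    row <- if (is.character(taxon)) match(taxon, ids) else as.integer(taxon)
    if (is.na(row) || row < 1 || row > nrow(ins$values))
      stop("unknown taxon: ", taxon)
    for (t in seq_along(ins$days)) {
      key <- as.character(ins$days[t])
      vals[[key]] <- c(vals[[key]], ins$values[row, t])
    }
  }
  days <- sort(as.numeric(names(vals)))
  qs <- t(vapply(as.character(days), function(k)
    stats::quantile(vals[[k]], probs = c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE),
    numeric(5)))
  out <- data.frame(day = days, q2.5 = qs[, 1], q25 = qs[, 2],
                    median = qs[, 3], q75 = qs[, 4], q97.5 = qs[, 5],
                    n = vapply(as.character(days), function(k) length(vals[[k]]), integer(1)))
  rownames(out) <- NULL
  out
}

#' Group/phase association analysis from counts to edges
#'
#' Convenience wrapper chaining [dirichlet_instances()] per animal and
#' [fit_gp_posterior()] over the animals of one group (optionally one
#' phase), then [summarize_associations()].
#'
#' @param table genus-level count table (raw counts).
#' @param metadata sample metadata (`sample_id`, `animal_id`, `group`,
#'   `day`, `phase`).
#' @param group experimental group to analyse.
#' @param phase optional phase filter (e.g. "recovery"); `NULL` keeps all
#'   post-pretreatment samples present in `table`.
#' @param config a [gp_config()].
#' @param strong_threshold passed to [summarize_associations()].
#' @param seed seed for the Dirichlet resampling and posterior draws.
#' @return list with `posterior` and `edges`.
#' @export
associate_group <- function(table, metadata, group, phase = NULL,
                            config = gp_config(), strong_threshold = 0.5,
                            seed = NULL) {
  set_seed_if(seed)
  md <- metadata[metadata$group == group & metadata$sample_id %in% colnames(table), , drop = FALSE]
  if (!is.null(phase)) md <- md[md$phase %in% phase, , drop = FALSE]
  instances <- list()
  for (animal in unique(md$animal_id)) {
    rows <- md[md$animal_id == animal, , drop = FALSE]
    rows <- rows[order(rows$day), , drop = FALSE]
    if (nrow(rows) < 3) next
    series <- table[, rows$sample_id, drop = FALSE]
    instances <- c(instances,
                   dirichlet_instances(series, days = rows$day,
                                       n_instances = config$n_instances,
                                       animal_id = animal))
  }
  if (length(instances) == 0) stop("no animal in group ", group, " has >= 3 timepoints")
  post <- fit_gp_posterior(instances, config,
                           provenance = list(group = group, phase = phase %||% "all"))
  list(posterior = post, edges = summarize_associations(post, strong_threshold))
}
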