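# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Squared-exponential (RBF) kernel over sampling days
#'
#' Builds the Gram matrix `variance * exp(-0.5 * (d_i - d_j)^2 / lengthscale^2)`
#' with an optional nugget (observation noise) on the diagonal. Used both by
#' the synthetic-data generator (temporal smoothness of latent log abundances)
#' and by the Gaussian-process covariation engine (column covariance over the
#' irregular sampling schedule).
#'
#' @param days numeric vector of observation days.
#' @param lengthscale kernel bandwidth in days; must be > 0.
#' @param variance marginal kernel variance.
#' @param nugget non-negative noise variance added to the diagonal.
#' @return a `length(days)` x `length(days)` covariance matrix.
#' @export
se_kernel <- function(days, lengthscale = 10, variance = 1, nugget = 0) {
  stopifnot(is.numeric(days), lengthscale > 0, variance > 0, nugget >= 0)
  d2 <- outer(days, days, "-")^2
  K <- variance * exp(-0.5 * d2 / lengthscale^2)
  if (nugget > 0) K <- K + diag(nugget, length(days))
  K
}

# set the RNG only when a seed is supplied; callers that want an untouched
# global stream pass seed = NULL
set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1)
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# smallest eigenvalue check used by PSD validators
min_eigen <- function(m) min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)

is_whole <- function(x, tol = 1e-8) all(abs(x - round(x)) < tol)

#' Validate a taxa-by-samples count table
#'
#' The count table is the universal currency between pipeline stages: a
#' non-negative integer matrix with unique taxon row names and unique sample
#' column names.
#'
#' @param x matrix to validate.
#' @return `x`, invisibly, with integer storage.
#' @export
validate_count_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("count table must be a numeric matrix (taxa x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("count table must carry taxon rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate taxon ids: ", paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids: ", paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (any(x < 0)) stop("count table contains negative values")
  if (!is_whole(x)) stop("count table contains non-integer values")
  storage.mode(x) <- "integer"
  invisible(x)
}

# canonical unordered pair key for edge comparisons
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}
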