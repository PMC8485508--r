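# penalized B-spline machinery for group trajectory smooths
#
# model: value ~ f_group(day) + animal intercept + noise, with a cubic
# B-spline f per group (second-difference penalty, shared smoothing
# parameter chosen by GCV) and ridge-penalized animal intercepts standing
# in for subject-level random effects.

spline_basis <- function(day, spec = NULL, n_knots = 10) {
  if (is.null(spec)) {
    interior <- unique(stats::quantile(day, probs = seq_len(n_knots) / (n_knots + 1),
                                       names = FALSE, type = 7))
    spec <- list(knots = interior, boundary = range(day), degree = 3)
  }
  B <- splines::bs(pmin(pmax(day, spec$boundary[1]), spec$boundary[2]),
                   knots = spec$knots, degree = spec$degree,
                   Boundary.knots = spec$boundary, intercept = TRUE)
  list(B = unclass(B)[, , drop = FALSE], spec = spec)
}

# design matrix: per-group spline blocks then animal dummies
build_design <- function(B, group, animal, groups, animals) {
  n <- nrow(B); k <- ncol(B)
  X <- matrix(0, n, k * length(groups) + length(animals))
  for (g in seq_along(groups)) {
    rows <- group == groups[g]
    X[rows, ((g - 1) * k + 1):(g * k)] <- B[rows, , drop = FALSE]
  }
  off <- k * length(groups)
  X[cbind(seq_len(n), off + match(animal, animals))] <- 1
  X
}

penalty_matrices <- function(k, n_groups, n_animals) {
  D2 <- diff(diag(k), differences = 2)
  Pk <- crossprod(D2)
  p <- k * n_groups + n_animals
  Ps <- matrix(0, p, p); Pa <- matrix(0, p, p)
  for (g in seq_len(n_groups)) {
    idx <- ((g - 1) * k + 1):(g * k)
    Ps[idx, idx] <- Pk
  }
  ai <- (k * n_groups + 1):p
  Pa[ai, ai] <- diag(n_animals)
  list(Ps = Ps, Pa = Pa)
}

pls_solve <- function(X, y, Ps, Pa, ls, la) {
  M <- crossprod(X) + ls * Ps + la * Pa
  ch <- tryCatch(chol(M + diag(1e-10, ncol(M))), error = function(e)
    stop("singular design: too few distinct days"))
  Minv <- chol2inv(ch)
  beta <- Minv %*% crossprod(X, y)
  fitted <- X %*% beta
  edf <- sum((X %*% Minv) * X)
  list(beta = beta, fitted = fitted, Minv = Minv, edf = edf,
       rss = sum((y - fitted)^2))
}

#' Fit group-specific smooth trajectories with animal intercepts
#'
#' Penalized cubic B-spline smooth per experimental group (second-difference
#' penalty, interior knots at day quantiles) plus ridge-penalized
#' animal-level intercepts, fitted by penalized least squares. The two
#' smoothing parameters (spline, animal ridge) are chosen by generalized
#' cross-validation on a logarithmic grid unless supplied. Pointwise 95\%
#' bands come from the Bayesian covariance of the penalized fit,
#' `sigma^2 (X'X + S_lambda)^-1`.
#'
#' @param series data.frame with columns `day`, `value`, `animal`, `group`.
#' @param n_knots interior knots (default 10, at day quantiles).
#' @param lambda optional fixed spline smoothing parameter.
#' @param lambda_animal optional fixed animal ridge parameter.
#' @param lambda_grid,lambda_animal_grid GCV search grids.
#' @param basis optional basis specification (list with `knots`, `boundary`,
#'   `degree`, as stored in a previous fit's `$basis`) overriding the
#'   quantile-based knot placement.
#' @param grid_length prediction-grid resolution over the day range.
#' @return object of class `trajectory_fit` with `grid` (group, day, mean,
#'   lo95, hi95), `lambda`, `lambda_animal`, `gcv`, `edf`, `sigma2`, the
#'   coefficient vector and basis specification.
#' @export
fit_group_smooths <- function(series, n_knots = 10,
                              lambda = NULL, lambda_animal = NULL,
                              lambda_grid = 10^seq(-4, 4, length.out = 17),
                              lambda_animal_grid = 10^seq(-2, 4, length.out = 7),
                              basis = NULL, grid_length = 100) {
  stopifnot(all(c("day", "value", "animal", "group") %in% names(series)))
  if (length(unique(series$day)) < 2) stop("singular design: only one unique day")
  groups <- sort(unique(as.character(series$group)))
  animals <- sort(unique(as.character(series$animal)))
  for (g in groups)
    if (sum(series$group == g) < 2) stop("group ", g, " has fewer than 2 observations")

  bs <- spline_basis(series$day, spec = basis, n_knots = n_knots)
  k <- ncol(bs$B)
  X <- build_design(bs$B, as.character(series$group), as.character(series$animal),
                    groups, animals)
  pen <- penalty_matrices(k, length(groups), length(animals))
  y <- series$value
  n <- length(y)

  ls_grid <- if (is.null(lambda)) lambda_grid else lambda
  la_grid <- if (is.null(lambda_animal)) lambda_animal_grid else lambda_animal
  best <- NULL
  for (la in la_grid) for (ls in ls_grid) {
    fit <- pls_solve(X, y, pen$Ps, pen$Pa, ls, la)
    gcv <- n * fit$rss / (n - fit$edf)^2
    if (is.null(best) || gcv < best$gcv)
      best <- c(fit, list(gcv = gcv, lambda = ls, lambda_animal = la))
  }
  sigma2 <- best$rss / (n - best$edf)

  day_grid <- seq(min(series$day), max(series$day), length.out = grid_length)
  Bg <- spline_basis(day_grid, spec = bs$spec)$B
  grid <- list()
  for (g in seq_along(groups)) {
    idx <- ((g - 1) * k + 1):(g * k)
    mu <- as.vector(Bg %*% best$beta[idx])
    Vg <- sigma2 * best$Minv[idx, idx]
    se <- sqrt(pmax(rowSums((Bg %*% Vg) * Bg), 0))
    grid[[g]] <- data.frame(group = groups[g], day = day_grid, mean = mu,
                            lo95 = mu - 1.96 * se, hi95 = mu + 1.96 * se)
  }
  structure(list(grid = do.call(rbind, grid), groups = groups,
                 animals = animals, beta = best$beta, basis = bs$spec,
                 lambda = best$lambda, lambda_animal = best$lambda_animal,
                 gcv = best$gcv, edf = best$edf, sigma2 = sigma2,
                 n_obs = n),
            class = "trajectory_fit")
}

#' Predict a group's fitted smooth at given days
#'
#' @param fit a `trajectory_fit`.
#' @param group group label.
#' @param days numeric days (clamped to the fitted range).
#' @return numeric vector of fitted means.
#' @export
predict_group_smooth <- function(fit, group, days) {
  g <- match(group, fit$groups)
  if (is.na(g)) stop("unknown group: ", group)
  k <- length(fit$basis$knots) + fit$basis$degree + 1
  B <- spline_basis(days, spec = fit$basis)$B
  as.vector(B %*% fit$beta[((g - 1) * k + 1):(g * k)])
}

smooth_contrast_stat <- function(fit, group_a, group_b, ngrid = 50) {
  dr <- fit$basis$boundary
  days <- seq(dr[1], dr[2], length.out = ngrid)
  diff2 <- (predict_group_smooth(fit, group_a, days) -
            predict_group_smooth(fit, group_b, days))^2
  mean(diff2) * (dr[2] - dr[1])   # integrated squared difference
}

#' Animal-level permutation contrast between two group trajectories
#'
#' Observed statistic: integrated squared difference between the two fitted
#' group smooths over the common day range. The null is built by permuting
#' group labels at the animal level (animals, not samples, are the
#' exchangeable units of this repeated-measures design) and refitting with
#' the smoothing parameters of the observed fit;
#' `p = (1 + #\{perm >= obs\}) / (1 + n_perm)`.
#'
#' @param series data.frame with `day`, `value`, `animal`, `group` and
#'   optionally `phase`.
#' @param group_a,group_b the two groups to contrast.
#' @param phase optional phase (or vector of phases) to restrict to.
#' @param n_perm number of permutations (default 999); 0 gives p = 1.
#' @param seed integer seed.
#' @param n_knots passed to [fit_group_smooths()].
#' @return list with `statistic`, `p`, `n_perm`, `phase`, `fit` (the
#'   observed two-group fit).
#' @export
compare_groups_permutation <- function(series, group_a, group_b, phase = NULL,
                                       n_perm = 999, seed = NULL, n_knots = 10) {
  if (!is.null(phase)) {
    stopifnot("phase" %in% names(series))
    series <- series[series$phase %in% phase, , drop = FALSE]
  }
  series <- series[series$group %in% c(group_a, group_b), , drop = FALSE]
  for (g in c(group_a, group_b))
    if (!g %in% series$group) stop("group ", g, " absent in the selected window")
  animals <- unique(series[, c("animal", "group")])
  if (any(table(animals$group) < 2))
    stop("need at least 2 animals per group for an animal-level permutation null")
  set_seed_if(seed)

  fit0 <- fit_group_smooths(series, n_knots = n_knots)
  obs <- smooth_contrast_stat(fit0, group_a, group_b)
  if (n_perm == 0)
    return(list(statistic = obs, p = 1, n_perm = 0, phase = phase, fit = fit0))

  labels <- animals$group
  perm_stats <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample(labels)
    pseries <- series
    pseries$group <- perm[match(series$animal, animals$animal)]
    pfit <- fit_group_smooths(pseries, n_knots = n_knots,
                              lambda = fit0$lambda,
                              lambda_animal = fit0$lambda_animal)
    perm_stats[b] <- smooth_contrast_stat(pfit, group_a, group_b)
  }
  p <- (1 + sum(perm_stats >= obs)) / (1 + n_perm)
  list(statistic = obs, p = p, n_perm = n_perm, phase = phase, fit = fit0,
       perm_stats = perm_stats)
}
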