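test_that("edge summaries compute medians, credible intervals and flags", {
  # all draws equal 0.7 for one pair -> degenerate CI, significant and strong
  arr <- array(0, c(2, 2, 10))
  arr[1, 1, ] <- arr[2, 2, ] <- 1
  arr[1, 2, ] <- arr[2, 1, ] <- 0.7
  ed <- summarize_associations(fake_posterior(arr))
  expect_equal(ed$rho_median, 0.7)
  expect_equal(ed$ci_low, 0.7)
  expect_equal(ed$ci_high, 0.7)
  expect_true(ed$significant && ed$strong)
  # draws symmetric around zero -> not significant
  arr[1, 2, ] <- arr[2, 1, ] <- seq(-0.5, 0.5, length.out = 10)
  ed0 <- summarize_associations(fake_posterior(arr))
  expect_false(ed0$significant)
  # strong is strict: |median| exactly at the threshold is not strong
  arr[1, 2, ] <- arr[2, 1, ] <- 0.5
  expect_false(summarize_associations(fake_posterior(arr))$strong)
})

test_that("pooled percentiles agree with analytic normal quantiles", {
  set.seed(13)
  n <- 10001
  draws <- pmin(pmax(rnorm(n, 0.6, 0.05), -1), 1)
  arr <- array(0, c(2, 2, n))
  arr[1, 1, ] <- arr[2, 2, ] <- 1
  arr[1, 2, ] <- arr[2, 1, ] <- draws
  ed <- summarize_associations(fake_posterior(arr))
  expect_equal(ed$rho_median, 0.6, tolerance = 0.01)
  expect_equal(ed$ci_low, qnorm(0.025, 0.6, 0.05), tolerance = 0.01)
  expect_equal(ed$ci_high, qnorm(0.975, 0.6, 0.05), tolerance = 0.01)
  expect_true(ed$significant && ed$strong)
})

test_that("conjugate posterior mean matches the closed-form inverse-Wishart mean", {
  # with K = I the posterior is IW(nu + T, Xi + SSE) and its mean has a
  # closed form; check the Monte-Carlo mean of covariance draws against it
  set.seed(17)
  D <- 3; Tn <- 40
  Sig <- diag(D); Sig[1, 2] <- Sig[2, 1] <- 0.6
  Y <- t(chol(Sig)) %*% matrix(rnorm(D * Tn), D, Tn)
  inst <- fake_instance(Y, days = seq_len(Tn))
  cfg <- gp_config(lengthscale = 1e-3, variance = 1, nugget = 0,
                   n_draws = 4000, seed = 18)
  post <- fit_gp_posterior(list(inst), cfg, correlation = FALSE)
  Yc <- Y - rowMeans(Y)
  SSE <- Yc %*% t(Yc)
  nu <- D + 3
  closed <- (diag(D) + SSE) / (nu + Tn - D - 1)
  mc_mean <- apply(post$draws, c(1, 2), mean)
  mc_se <- apply(post$draws, c(1, 2), sd) / sqrt(cfg$n_draws)
  expect_true(all(abs(mc_mean - closed) <= 3 * mc_se))
})

test_that("posterior correlation draws are valid correlation matrices", {
  out <- sim_group_instances(seed = 21, n_taxa = 8, n_animals = 1,
                             n_instances = 4)
  post <- fit_gp_posterior(out$instances, gp_config(n_draws = 10, seed = 22))
  for (i in seq_len(dim(post$draws)[3])) {
    R <- post$draws[, , i]
    expect_equal(R, t(R), tolerance = 1e-10)
    expect_equal(diag(R), rep(1, 8), ignore_attr = TRUE, tolerance = 1e-10)
    expect_true(all(abs(R) <= 1 + 1e-10))
    expect_gte(min_eig <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("null posterior covers zero and pooling identical evidence never widens the CI", {
  # D = 2 independent rows, K = I: median near 0 and CI covering 0
  set.seed(23)
  covered <- 0
  for (s in 1:20) {
    Y <- matrix(rnorm(2 * 50), 2, 50)
    inst <- fake_instance(Y, days = 1:50)
    post <- fit_gp_posterior(list(inst),
                             gp_config(lengthscale = 1e-3, variance = 1,
                                       nugget = 0, n_draws = 100, seed = s))
    ed <- summarize_associations(post)
    expect_lt(abs(ed$rho_median), 0.35)
    if (!ed$significant) covered <- covered + 1
  }
  expect_gte(covered, 18)   # 95% CI covers 0 in >= 90% of replicates
  # duplicating the pooled draw set leaves median and CI unchanged
  out <- sim_group_instances(seed = 24, n_taxa = 6, n_animals = 1, n_instances = 4)
  post <- fit_gp_posterior(out$instances, gp_config(n_draws = 20, seed = 25))
  ed1 <- summarize_associations(post)
  post2 <- post
  post2$draws <- array(c(post$draws, post$draws), dim = dim(post$draws) * c(1, 1, 2),
                       dimnames = dimnames(post$draws))
  ed2 <- summarize_associations(post2)
  expect_equal(ed2$rho_median, ed1$rho_median)
  expect_true(all(ed2$ci_high - ed2$ci_low <= ed1$ci_high - ed1$ci_low + 1e-12))
})

test_that("planted strong pairs are recovered with correct signs", {
  out <- sim_group_instances(seed = 31, n_taxa = 20, n_animals = 3,
                             n_pos = 3, n_neg = 2, n_instances = 32)
  post <- fit_gp_posterior(out$instances, gp_config(n_draws = 50, seed = 32))
  ed <- summarize_associations(post)
  keys <- planted_pair_keys(out$truth, rownames(out$sim$counts))
  got <- ed[match(keys, edge_keys(ed)), ]
  expect_gte(mean(abs(got$rho_median) > 0.5), 0.6)
  det <- abs(got$rho_median) > 0.5
  expect_equal(sum(sign(got$rho_median[det]) != sign(out$truth$planted_rho[det])), 0)
})

test_that("kernel degenerates with duplicate days unless a nugget is used", {
  Y <- matrix(rnorm(4 * 6), 4, 6)
  inst <- structure(list(values = Y, instance_index = 1L, animal_id = "a",
                         days = c(1, 1, 2, 3, 4, 5)), class = "clr_instance")
  expect_error(fit_gp_posterior(list(inst), gp_config(nugget = 0, n_draws = 2)),
               "nugget")
  expect_silent(fit_gp_posterior(list(inst), gp_config(nugget = 0.1, n_draws = 2, seed = 1)))
})

test_that("network comparison reports shared and unique edges by sign", {
  mk <- function(pairs, signs) {
    data.frame(taxon_i = pairs[, 1], taxon_j = pairs[, 2],
               rho_median = 0.8 * signs, ci_low = 0.6 * signs,
               ci_high = 0.9 * signs, significant = TRUE, strong = TRUE,
               sign = signs, stringsAsFactors = FALSE)
  }
  a <- mk(rbind(c("x", "y"), c("x", "z")), c(1, -1))
  b <- mk(rbind(c("y", "x")), 1)                      # order-insensitive
  cmp <- compare_networks(a, b)
  expect_equal(unname(cmp$counts["n_shared"]), 1)
  expect_equal(unname(cmp$counts["n_shared_positive"]), 1)
  expect_equal(unname(cmp$counts["n_unique_a"]), 1)
  expect_equal(unname(cmp$counts["n_sign_flips"]), 0)
  # identical lists: all shared; disjoint: none
  self <- compare_networks(a, a)
  expect_equal(unname(self$counts["n_shared"]), 2)
  expect_equal(unname(self$counts["n_unique_a"]), 0)
  disj <- compare_networks(a, mk(rbind(c("p", "q")), 1))
  expect_equal(unname(disj$counts["n_shared"]), 0)
})

test_that("log-ratio trajectories track a taxon's share and stay flat when constant", {
  # constant composition -> flat median
  tab <- toy_table(matrix(rep(c(500L, 300L, 200L), 6), nrow = 3))
  inst <- dirichlet_instances(tab, n_instances = 100, seed = 41)
  traj <- log_ratio_trajectory(inst, "t1")
  expect_lt(diff(range(traj$median)), 0.15)
  expect_true(all(traj$q2.5 <= traj$median & traj$median <= traj$q97.5))
  # taxon rising 10x while others constant -> strictly increasing median
  rising <- toy_table(rbind(seq(100L, 1000L, length.out = 6),
                            rep(500L, 6), rep(500L, 6)))
  inst2 <- dirichlet_instances(rising, n_instances = 100, seed = 42)
  traj2 <- log_ratio_trajectory(inst2, "t1")
  expect_true(all(diff(traj2$median) > 0))
  expect_error(log_ratio_trajectory(inst2, "nope"), "unknown taxon")
})

test_that("clr-scale correlation is invariant to per-sample depth rescaling", {
  set.seed(43)
  tab <- toy_table(matrix(rpois(5 * 10, 200) + 1L, 5, 10))
  inst1 <- dirichlet_instances(tab, n_instances = 64, seed = 44)
  scaled <- tab * 4L                                  # 4x sequencing depth
  inst2 <- dirichlet_instances(scaled, n_instances = 64, seed = 44)
  m1 <- rowMeans(sapply(inst1, function(i) as.vector(i$values)))
  m2 <- rowMeans(sapply(inst2, function(i) as.vector(i$values)))
  expect_equal(m1, m2, tolerance = 0.05)              # same CLR location
})
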