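test_that("sum of variances matches hand cases and the covariance-trace oracle", {
  x <- rbind(c(0, 0), c(1, 0), c(2, 0))
  expect_equal(sum_of_variances(x), 1)
  expect_equal(sum_of_variances(rbind(c(3, 4), c(3, 4), c(3, 4))), 0)
  expect_error(sum_of_variances(x[1, , drop = FALSE]), "fewer than 2")

  set.seed(2)
  y <- matrix(rnorm(20 * 6), 20, 6)
  expect_equal(sum_of_variances(y), sum(diag(cov(y))), tolerance = 1e-12)

  # invariant under rotation and translation; scales as c^2
  q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  expect_equal(sum_of_variances(sweep(y %*% q, 2, rnorm(6), "+")),
               sum_of_variances(y), tolerance = 1e-10)
  expect_equal(sum_of_variances(3 * y), 9 * sum_of_variances(y),
               tolerance = 1e-10)
})

test_that("disparity on all PCo axes equals disparity on the standardized characters", {
  tab <- simulate_assemblage(simulation_config(seed = 5))
  std <- zscore_matrix(character_matrix(tab))
  ord <- pcoa(euclidean_distances(std))
  for (g in c("Cut", "Pierce II")) {
    idx <- which(tab$records$guild == g)
    expect_equal(sum_of_variances(ord$coordinates[idx, ]),
                 sum_of_variances(std$values[idx, ]),
                 tolerance = 1e-8)
  }
})

test_that("bootstrap disparity is seeded, degenerate-safe, and covers the true trace", {
  set.seed(3)
  x <- matrix(rnorm(15 * 3), 15, 3)
  b1 <- bootstrap_disparity(x, n_bootstrap = 200, seed = 42)
  b2 <- bootstrap_disparity(x, n_bootstrap = 200, seed = 42)
  expect_identical(b1$distribution, b2$distribution)
  expect_true(b1$ci[1] <= b1$observed || b1$ci[2] >= b1$observed)

  z <- matrix(1, 5, 2)  # zero spread
  bz <- bootstrap_disparity(z, n_bootstrap = 50, seed = 1)
  expect_equal(unique(bz$distribution), 0)
  expect_equal(bz$ci, c(0, 0))

  # 95% percentile CI covers the true trace at close to nominal rate
  set.seed(99)
  true_trace <- 3  # identity covariance in 3 dimensions
  hits <- replicate(400, {
    g <- matrix(rnorm(20 * 3), 20, 3)
    ci <- bootstrap_disparity(g, n_bootstrap = 300,
                              seed = sample.int(1e6, 1))$ci
    ci[1] <= true_trace && true_trace <= ci[2]
  })
  expect_gte(mean(hits), 0.88)
  expect_lte(mean(hits), 0.99)
})

test_that("the disparity permutation test is exact on small groups and symmetric", {
  set.seed(6)
  x <- matrix(rnorm(6 * 2), 6, 2,
              dimnames = list(sprintf("s%d", 1:6), NULL))
  res <- disparity_permutation_test(x, 1:3, 4:6)
  expect_identical(res$method, "exhaustive")
  expect_equal(res$n_permutations, 20)

  # independent enumeration oracle over all 20 splits
  splits <- utils::combn(6, 3)
  deltas <- apply(splits, 2, function(idx) {
    sum(apply(x[idx, ], 2, var)) - sum(apply(x[-idx, ], 2, var))
  })
  obs <- sum(apply(x[1:3, ], 2, var)) - sum(apply(x[4:6, ], 2, var))
  expect_equal(res$observed_difference, obs, tolerance = 1e-12)
  expect_equal(res$p, mean(abs(deltas) >= abs(obs) - 1e-12))

  # two-tailed symmetry in the group order
  res_ba <- disparity_permutation_test(x, 4:6, 1:3)
  expect_equal(res_ba$p, res$p)
  expect_equal(res_ba$observed_difference, -res$observed_difference)

  # duplicated cloud: zero difference, p = 1 under the >= counting rule
  y <- rbind(x[1:3, ], x[1:3, ])
  rownames(y) <- sprintf("r%d", 1:6)
  dup <- disparity_permutation_test(y, 1:3, 4:6)
  expect_equal(dup$observed_difference, 0)
  expect_equal(dup$p, 1)

  expect_error(disparity_permutation_test(x, 1:3, 3:6), "overlap")
})

test_that("rank-sum comparisons of bootstrap distributions count pairs and clip ties", {
  set.seed(8)
  boots <- list(a = rnorm(100), b = rnorm(100), c = rnorm(100) + 20,
                d = rnorm(100))
  wx <- disparity_wilcoxon_matrix(boots)
  expect_equal(nrow(wx), choose(4, 2))
  expect_equal(wx$p_bonferroni, pmin(1, 6 * wx$p_raw))
  # totally separated pair is at the test's minimum attainable value
  ac <- wx[wx$group_A == "a" & wx$group_B == "c", ]
  min_p <- min(wx$p_raw)
  expect_equal(ac$p_raw, min_p)
  expect_lt(ac$p_bonferroni, 0.001)
  # a distribution against an identical copy: p = 1, not NaN
  same <- disparity_wilcoxon_matrix(list(a = rep(2, 50), b = rep(2, 50)))
  expect_equal(same$p_raw, 1)
  expect_error(disparity_wilcoxon_matrix(list(a = 1:5, b = 1:4)),
               "equal length")
})

test_that("the grouped disparity analysis bundles estimates, intervals and pairwise tests", {
  tab <- simulate_assemblage(simulation_config(
    design = balanced_design(6), seed = 13))
  std <- zscore_matrix(character_matrix(tab))
  da <- disparity_analysis(std$values, tab$records$guild,
                           n_bootstrap = 100, n_permutations = 99,
                           seed = 7)
  expect_equal(nrow(da$per_group), 6)
  expect_true(all(da$per_group$sum_of_variances >= 0))
  expect_true(all(da$per_group$ci_low <= da$per_group$sum_of_variances +
                    1e-12))
  expect_equal(nrow(da$pairwise), choose(6, 2))
  expect_true(all(!is.na(da$pairwise$p_wilcoxon_bonferroni)))
  # antisymmetry of the observed difference is respected in storage
  expect_true(all(da$pairwise$group_A < da$pairwise$group_B))
})
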