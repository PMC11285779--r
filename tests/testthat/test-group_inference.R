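# independent enumeration oracle: pseudo-F from group centroids,
# p as the exact fraction of 3|3 splits with F at least the observed
oracle_f <- function(x, labels) {
  groups <- unique(labels)
  n <- nrow(x); g <- length(groups)
  grand <- colMeans(x)
  ssw <- 0; ssb <- 0
  for (gr in groups) {
    xs <- x[labels == gr, , drop = FALSE]
    cen <- colMeans(xs)
    ssw <- ssw + sum(sweep(xs, 2, cen)^2)
    ssb <- ssb + nrow(xs) * sum((cen - grand)^2)
  }
  (ssb / (g - 1)) / (ssw / (n - g))
}

test_that("the exact 3|3 permutation p equals exhaustive enumeration by an independent oracle", {
  set.seed(21)
  x <- matrix(rnorm(6 * 3), 6, 3,
              dimnames = list(sprintf("s%d", 1:6), NULL))
  labels <- rep(c("A", "B"), each = 3)
  res <- permanova_oneway(x, labels, n_permutations = "exhaustive")
  expect_identical(res$method, "exhaustive")
  expect_equal(res$n_permutations, 20)
  expect_equal(res$pseudo_F, oracle_f(x, labels), tolerance = 1e-10)

  splits <- utils::combn(6, 3)
  f_all <- apply(splits, 2, function(idx) {
    lab <- rep("B", 6); lab[idx] <- "A"
    oracle_f(x, lab)
  })
  p_oracle <- mean(f_all >= res$pseudo_F - 1e-12)
  expect_equal(res$p_raw, p_oracle)
})

test_that("maximally separated clusters attain the permutation floor", {
  # equal 3|3 sizes: the observed partition appears twice among the 20
  # label arrangements (label swap), so the exact floor is 2/20
  cl <- two_clusters(n_per = 3, sep = 100, p = 2, seed = 5)
  res <- permanova_oneway(cl$x, cl$labels)   # auto-exhaustive, 20 splits
  expect_identical(res$method, "exhaustive")
  expect_equal(res$p_raw, 2 / 20)
  # groups large enough that re-drawing the observed partition is
  # negligible reach the Monte-Carlo floor 1/(B+1)
  cl2 <- two_clusters(n_per = 10, sep = 100, p = 2, seed = 5)
  res_mc <- permanova_oneway(cl2$x, cl2$labels, n_permutations = 99,
                             seed = 2, exhaustive_limit = 1)
  expect_equal(res_mc$p_raw, 1 / 100)
})

test_that("p-values are invariant to specimen order and group renaming under one seed", {
  set.seed(31)
  x <- matrix(rnorm(24 * 4), 24, 4,
              dimnames = list(sprintf("s%02d", 1:24), NULL))
  labels <- rep(c("A", "B", "C"), each = 8)
  r1 <- permanova_oneway(x, labels, n_permutations = 199, seed = 10,
                         exhaustive_limit = 1)
  o <- sample(24)
  r2 <- permanova_oneway(x[o, ], labels[o], n_permutations = 199,
                         seed = 10, exhaustive_limit = 1)
  expect_equal(r2$pseudo_F, r1$pseudo_F, tolerance = 1e-12)
  expect_equal(r2$p_raw, r1$p_raw)
  relabel <- c(A = "Zeta", B = "Eta", C = "Theta")[labels]
  r3 <- permanova_oneway(x, relabel, n_permutations = 199, seed = 10,
                         exhaustive_limit = 1)
  expect_equal(r3$p_raw, r1$p_raw)
})

test_that("the pseudo-F agrees with vegan's adonis2 and the full-axis test equals the character-space test", {
  tab <- simulate_assemblage(simulation_config(
    design = balanced_design(5), seed = 14))
  std <- zscore_matrix(character_matrix(tab))
  ord <- pcoa(euclidean_distances(std))
  labels <- tab$records$guild

  r_chars <- permanova_oneway(std, labels, n_permutations = 99, seed = 4,
                              exhaustive_limit = 1)
  r_pco <- permanova_oneway(ord, labels, n_permutations = 99, seed = 4,
                            exhaustive_limit = 1)
  # Euclidean geometry is preserved by the ordination
  expect_equal(r_pco$pseudo_F, r_chars$pseudo_F, tolerance = 1e-10)
  expect_equal(r_pco$p_raw, r_chars$p_raw)

  ad <- vegan::adonis2(dist(std$values) ~ g,
                       data = data.frame(g = labels), permutations = 2)
  expect_equal(r_chars$pseudo_F, ad$F[1], tolerance = 1e-10)
})

test_that("pairwise PERMANOVA enumerates pairs and orders its corrected columns", {
  tab <- simulate_assemblage(simulation_config(
    design = balanced_design(5), seed = 8))
  std <- zscore_matrix(character_matrix(tab))
  pw <- permanova_pairwise(std, tab$records$guild, n_permutations = 99,
                           seed = 3)
  expect_equal(nrow(pw), choose(6, 2))
  expect_equal(attr(pw, "m"), 15)
  expect_equal(pw$p_bonferroni, pmin(1, 15 * pw$p_raw))
  # hand step-up check of the Benjamini-Hochberg column
  m <- nrow(pw)
  o <- order(pw$p_raw)
  bh <- rev(cummin(rev(pw$p_raw[o] * m / seq_len(m))))
  expect_equal(pw$p_bh[o], pmin(1, bh))
  expect_true(all(pw$p_bonferroni >= pw$p_bh - 1e-12))
  expect_true(all(pw$p_bh >= pw$p_raw - 1e-12))
  # square-matrix layout is symmetric with an empty diagonal
  pm <- pairwise_matrix(pw)
  expect_true(isSymmetric(pm))
  expect_true(all(is.na(diag(pm))))

  # undersized groups are skipped and recorded
  labs <- tab$records$guild
  labs[labs == "Smash"][1:3] <- "Cut"   # leaves Smash with 2 members
  expect_warning(
    pw2 <- permanova_pairwise(std, labs, n_permutations = 99, seed = 3),
    "Smash")
  expect_equal(attr(pw2, "skipped"), "Smash")
  expect_equal(nrow(pw2), choose(5, 2))
})

test_that("jackknifed LDA is perfect on separated clusters and matches MASS leave-one-out", {
  cl <- two_clusters(n_per = 10, sep = 100, p = 3, seed = 2)
  res <- lda_jackknife(cl$x, cl$labels)
  expect_equal(res$overall_jackknife_rate, 1.0)
  expect_equal(unname(rowSums(res$confusion_matrix)), c(10, 10))

  # overlapping clusters: cross-check each held-out prediction
  cl2 <- two_clusters(n_per = 12, sep = 1.2, p = 4, seed = 3)
  ours <- lda_jackknife(cl2$x, cl2$labels)
  mass <- MASS::lda(cl2$x, grouping = cl2$labels,
                    prior = c(0.5, 0.5), CV = TRUE)
  cm_mass <- table(true = cl2$labels, predicted = mass$class)
  expect_equal(unclass(ours$confusion_matrix), unclass(cm_mass),
               ignore_attr = TRUE)
})

test_that("the fitted two-class discriminant direction matches the Fisher closed form", {
  cl <- two_clusters(n_per = 15, sep = 2, p = 4, seed = 9)
  fit <- jawspace:::lda_pooled_fit(cl$x, cl$labels)
  w_dir <- fit$weights[, 1] - fit$weights[, 2]
  dmean <- fit$means[1, ] - fit$means[2, ]
  fisher <- solve(fit$pooled_cov, dmean)
  cos_angle <- sum(w_dir * fisher) /
    sqrt(sum(w_dir^2) * sum(fisher^2))
  expect_gt(cos_angle, 0.999)
})

test_that("LDA on permuted labels recovers only chance-level accuracy", {
  set.seed(17)
  x <- matrix(rnorm(24 * 4), 24, 4)
  labels <- rep(c("A", "B", "C"), each = 8)
  rates <- replicate(200, {
    lda_jackknife(x, sample(labels))$overall_jackknife_rate
  })
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 1 / 3), 3 * se + 0.02)
})
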