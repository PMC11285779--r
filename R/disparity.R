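#' Sum-of-variances disparity of a group
#'
#' Morphofunctional variety measured as the sum over axes of the
#' sample variance (denominator `n - 1`) of the group members' scores;
#' equal to the trace of the members' covariance matrix.  Computed
#' over all retained ordination axes this is basis-invariant and
#' identical to the value obtained on the z-scored characters
#' themselves.
#'
#' @param coords specimens-by-axes matrix (or `jaw_pcoa` /
#'   `std_matrix`).
#' @param members row selector for the group: specimen ids (matched
#'   against row names), integer indices or a logical vector.  Default
#'   uses all rows.
#' @return non-negative scalar.
#' @export
sum_of_variances <- function(coords, members = NULL) {
  x <- as.matrix(if (inherits(coords, "jaw_pcoa")) coords$coordinates
                 else if (inherits(coords, "std_matrix")) coords$values
                 else coords)
  x <- select_rows(x, members)
  if (nrow(x) < 2) stop("disparity undefined for fewer than 2 members")
  sum(apply(x, 2, stats::var))
}

select_rows <- function(x, members) {
  if (is.null(members)) return(x)
  if (is.character(members)) {
    idx <- match(members, rownames(x))
    if (anyNA(idx)) {
      stop("unknown specimen id(s): ",
           paste(members[is.na(idx)], collapse = ", "))
    }
    members <- idx
  }
  x[members, , drop = FALSE]
}

#' Bootstrap distribution of sum-of-variances disparity
#'
#' Resamples the group members with replacement and recomputes the
#' sum of variances `n_bootstrap` times, returning the distribution
#' and a 95% percentile interval.
#'
#' @inheritParams sum_of_variances
#' @param n_bootstrap number of bootstrap resamples (default 1000).
#' @param seed integer seed (required).
#' @return list with `observed`, `distribution`, `ci` (2.5 and 97.5
#'   percentiles), `n`, `n_bootstrap`, `seed`.
#' @export
bootstrap_disparity <- function(coords, members = NULL,
                                n_bootstrap = 1000, seed) {
  x <- as.matrix(if (inherits(coords, "jaw_pcoa")) coords$coordinates
                 else if (inherits(coords, "std_matrix")) coords$values
                 else coords)
  x <- select_rows(x, members)
  n <- nrow(x)
  if (n < 3) stop("bootstrap disparity needs at least 3 members")
  set.seed(seed)
  dist_boot <- vapply(seq_len(n_bootstrap), function(b) {
    xb <- x[sample.int(n, n, replace = TRUE), , drop = FALSE]
    sum(apply(xb, 2, stats::var))
  }, numeric(1))
  ci <- stats::quantile(dist_boot, c(0.025, 0.975), names = FALSE)
  list(observed = sum(apply(x, 2, stats::var)),
       distribution = dist_boot, ci = ci, n = n,
       n_bootstrap = n_bootstrap, seed = seed)
}

## SoV from squared pairwise distances: trace of covariance equals
## sum_{i<j} d_ij^2 / (n (n - 1)) -- used to vectorize permutations
sov_from_d2 <- function(d2, indicator, n_g) {
  colSums(indicator * (d2 %*% indicator)) / (2 * n_g * (n_g - 1))
}

#' Permutation test for a disparity difference between two groups
#'
#' Tests the observed difference in sum-of-variances disparity,
#' `SoV(A) - SoV(B)`, against a null built by pooling the members of
#' both groups and randomly re-splitting them at the original sizes.
#' Two-tailed: `p` counts permuted `|difference|` at least as large as
#' observed.  When the number of distinct splits is at most
#' `exhaustive_limit` every split is enumerated and the p-value is
#' exact (the observed split counts itself).
#'
#' @inheritParams sum_of_variances
#' @param members_a,members_b disjoint row selectors for the two
#'   groups.
#' @param n_permutations Monte-Carlo draws (default 9999) or
#'   `"exhaustive"`.
#' @param seed integer seed (required for Monte-Carlo).
#' @param exhaustive_limit exact enumeration threshold (default 1e5).
#' @return list with `observed_difference`, `sov_a`, `sov_b`, `p`,
#'   `method`, `n_permutations`, `seed`.
#' @export
disparity_permutation_test <- function(coords, members_a, members_b,
                                       n_permutations = 9999,
                                       seed = NULL,
                                       exhaustive_limit = 1e5) {
  x <- as.matrix(if (inherits(coords, "jaw_pcoa")) coords$coordinates
                 else if (inherits(coords, "std_matrix")) coords$values
                 else coords)
  if ((is.character(members_a) || is.numeric(members_a)) &&
      length(intersect(members_a, members_b))) {
    stop("groups overlap: ",
         paste(intersect(members_a, members_b), collapse = ", "))
  }
  xa <- select_rows(x, members_a)
  xb <- select_rows(x, members_b)
  if (!is.null(rownames(xa)) &&
      length(intersect(rownames(xa), rownames(xb)))) {
    stop("groups overlap: ",
         paste(intersect(rownames(xa), rownames(xb)), collapse = ", "))
  }
  na <- nrow(xa); nb <- nrow(xb)
  if (na < 2 || nb < 2) stop("both groups need at least 2 members")
  pooled <- rbind(xa, xb)
  d2 <- as.matrix(stats::dist(pooled))^2
  n <- na + nb
  obs_a <- sum(d2[seq_len(na), seq_len(na)]) / (2 * na * (na - 1))
  obs_b <- sum(d2[na + seq_len(nb), na + seq_len(nb)]) /
    (2 * nb * (nb - 1))
  delta_obs <- obs_a - obs_b

  n_splits <- choose(n, na)
  if (identical(n_permutations, "exhaustive") ||
      n_splits <= exhaustive_limit) {
    picks <- utils::combn(n, na)
    za <- matrix(0, n, ncol(picks))
    za[cbind(as.vector(picks),
             rep(seq_len(ncol(picks)), each = na))] <- 1
    delta <- sov_from_d2(d2, za, na) - sov_from_d2(d2, 1 - za, nb)
    p <- mean(abs(delta) >= abs(delta_obs) - 1e-12)
    method <- "exhaustive"; nper <- ncol(picks)
  } else {
    if (is.null(seed)) stop("seed is required for Monte-Carlo permutations")
    set.seed(seed)
    nper <- as.integer(n_permutations)
    za <- matrix(0, n, nper)
    for (j in seq_len(nper)) za[sample.int(n, na), j] <- 1
    delta <- sov_from_d2(d2, za, na) - sov_from_d2(d2, 1 - za, nb)
    p <- (sum(abs(delta) >= abs(delta_obs) - 1e-12) + 1) / (nper + 1)
    method <- "monte-carlo"
  }
  list(observed_difference = delta_obs, sov_a = obs_a, sov_b = obs_b,
       p = p, method = method, n_permutations = nper, seed = seed)
}

#' Rank-sum comparisons between bootstrap disparity distributions
#'
#' Two-sample Wilcoxon rank-sum test on every pair of per-group
#' bootstrap sum-of-variances distributions, Bonferroni-corrected over
#' the number of pairs.  Note that bootstrap replicates are
#' pseudo-replicates of the same specimens, which makes these tests
#' anti-conservative; [disparity_permutation_test()] is the
#' recommended primary test, and this table is provided for
#' comparability with common practice.
#'
#' @param boot_dists named list of equal-length numeric vectors, one
#'   bootstrap distribution per group.
#' @return data frame with columns `group_A`, `group_B`, `statistic`,
#'   `p_raw`, `p_bonferroni`; attribute `m` holds the number of
#'   comparisons.
#' @export
disparity_wilcoxon_matrix <- function(boot_dists) {
  stopifnot(is.list(boot_dists), length(boot_dists) >= 2,
            !is.null(names(boot_dists)))
  lens <- lengths(boot_dists)
  if (length(unique(lens)) != 1) {
    stop("bootstrap distributions must have equal length")
  }
  pairs <- utils::combn(sort(names(boot_dists)), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    xa <- boot_dists[[a]]; xb <- boot_dists[[b]]
    if (all(xa == xa[1]) && all(xb == xb[1]) && xa[1] == xb[1]) {
      w <- length(xa) * length(xb) / 2; p <- 1
    } else {
      wt <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE))
      w <- unname(wt$statistic); p <- wt$p.value
      if (!is.finite(p)) p <- 1
    }
    data.frame(group_A = a, group_B = b, statistic = w, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  attr(out, "m") <- nrow(out)
  out
}

#' Per-group disparity analysis with pairwise tests
#'
#' Convenience wrapper running, for every group meeting the minimum
#' size: the point estimate of sum-of-variances disparity, a bootstrap
#' percentile interval, and the pairwise permutation and bootstrap
#' rank-sum tests between groups.
#'
#' @inheritParams sum_of_variances
#' @param labels group label per specimen (aligned with rows).
#' @param n_bootstrap,n_permutations resampling effort.
#' @param seed integer seed.
#' @param min_group_size smallest group analysed (default 3).
#' @return object of class `disparity_result`: `per_group` data frame
#'   (`group`, `n`, `sum_of_variances`, `ci_low`, `ci_high`),
#'   `bootstrap` (named list of distributions), `pairwise` data frame
#'   (`group_A`, `group_B`, `observed_difference`, `p_permutation`,
#'   `p_wilcoxon_bonferroni`), and the resampling parameters.
#' @export
disparity_analysis <- function(coords, labels, n_bootstrap = 1000,
                               n_permutations = 9999, seed,
                               min_group_size = 3) {
  x <- as.matrix(if (inherits(coords, "jaw_pcoa")) coords$coordinates
                 else if (inherits(coords, "std_matrix")) coords$values
                 else coords)
  labels <- as.character(labels)
  keep <- groups_testable(labels, min_group_size)
  if (length(keep) < 1) stop("no group meets the minimum size")
  keep <- sort(keep)
  boot <- list(); per <- list()
  for (i in seq_along(keep)) {
    g <- keep[i]
    bg <- bootstrap_disparity(x, which(labels == g),
                              n_bootstrap = n_bootstrap,
                              seed = seed + i)
    boot[[g]] <- bg$distribution
    per[[g]] <- data.frame(group = g, n = bg$n,
                           sum_of_variances = bg$observed,
                           ci_low = bg$ci[1], ci_high = bg$ci[2],
                           stringsAsFactors = FALSE)
  }
  pairwise <- NULL
  if (length(keep) >= 2) {
    wx <- disparity_wilcoxon_matrix(boot)
    pairs <- utils::combn(keep, 2)
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      pt <- disparity_permutation_test(
        x, which(labels == a), which(labels == b),
        n_permutations = n_permutations, seed = seed + 1000 + k)
      data.frame(group_A = a, group_B = b,
                 observed_difference = pt$observed_difference,
                 p_permutation = pt$p, stringsAsFactors = FALSE)
    })
    pairwise <- do.call(rbind, rows)
    pairwise$p_wilcoxon_bonferroni <-
      wx$p_bonferroni[match(paste(pairwise$group_A, pairwise$group_B),
                            paste(wx$group_A, wx$group_B))]
  }
  structure(list(per_group = do.call(rbind, per), bootstrap = boot,
                 pairwise = pairwise, n_bootstrap = n_bootstrap,
                 n_permutations = n_permutations, seed = seed),
            class = "disparity_result")
}

#' @export
print.disparity_result <- function(x, ...) {
  cat("Sum-of-variances disparity (", x$n_bootstrap, " bootstraps, ",
      x$n_permutations, " permutations)\n", sep = "")
  print(x$per_group, row.names = FALSE)
  invisible(x)
}
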