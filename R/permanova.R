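#' @section Distance-based sums of squares:
#' For a set of points and group labels, the total and within-group
#' sums of squared deviations from centroids are computed directly
#' from squared pairwise distances (Gower's identity):
#' `SS = sum_{i<j in g} d_ij^2 / n_g`.  This makes the pseudo-F
#' identical whether computed from coordinates or from the distance
#' matrix, and is what guarantees that a test on all PCo axes equals
#' the test on the z-scored characters they embed.
#' @name permanova-internals
#' @keywords internal
NULL

## decide whether input is a distance matrix or raw coordinates
as_squared_distance <- function(x) {
  x <- as.matrix(if (inherits(x, "jaw_pcoa")) x$coordinates else
                 if (inherits(x, "std_matrix")) x$values else x)
  is_dist <- nrow(x) == ncol(x) && all(abs(diag(x)) < 1e-12) &&
    max(abs(x - t(x))) < 1e-10 && all(x >= 0)
  if (is_dist) x^2 else as.matrix(stats::dist(x))^2
}

## SS_within for many labelings at once; labels_mat is n x P integer
## matrix (values 1..g), counts the fixed per-group sizes
within_ss_batch <- function(d2, labels_mat, counts) {
  ssw <- numeric(ncol(labels_mat))
  for (g in seq_along(counts)) {
    z <- (labels_mat == g) + 0
    ssw <- ssw + colSums(z * (d2 %*% z)) / (2 * counts[g])
  }
  ssw
}

pseudo_f <- function(ss_total, ss_within, n, g) {
  ((ss_total - ss_within) / (g - 1)) / (ss_within / (n - g))
}

## all distinct arrangements of a label multiset, as an n x N integer
## matrix; only call when the multinomial count is small
enumerate_arrangements <- function(counts) {
  n <- sum(counts)
  if (length(counts) == 2) {
    picks <- utils::combn(n, counts[1])
    m <- matrix(2L, n, ncol(picks))
    m[cbind(as.vector(picks),
            rep(seq_len(ncol(picks)), each = counts[1]))] <- 1L
    return(m)
  }
  recurse <- function(positions, k) {
    if (k == length(counts)) {
      m <- matrix(0L, n, 1)
      m[positions, 1] <- k
      return(m)
    }
    picks <- utils::combn(positions, counts[k])
    cols <- lapply(seq_len(ncol(picks)), function(j) {
      rest <- recurse(setdiff(positions, picks[, j]), k + 1)
      rest[picks[, j], ] <- k
      rest
    })
    do.call(cbind, cols)
  }
  recurse(seq_len(n), 1)
}

n_arrangements <- function(counts) {
  exp(lfactorial(sum(counts)) - sum(lfactorial(counts)))
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a coordinate
#' matrix (e.g. all PCo axes, or the z-scored characters directly) or
#' a ready-made distance matrix.  The pseudo-F statistic is
#' `(SS_between/(g-1)) / (SS_within/(n-g))` with sums of squares
#' computed from squared inter-point distances; the null distribution
#' is built by permuting group labels.
#'
#' When the number of distinct label arrangements does not exceed
#' `exhaustive_limit` the test is exact: every arrangement is
#' enumerated and `p` is the fraction with pseudo-F at least the
#' observed value (the observed arrangement counts itself, so `p > 0`).
#' Otherwise `n_permutations` Monte-Carlo draws are used with the
#' add-one correction `p = (#{F* >= F} + 1) / (n_permutations + 1)`.
#'
#' Specimens are canonically ordered by id before permuting, so the
#' result is invariant to input row order and to renaming groups.
#'
#' @param x coordinates (matrix, `std_matrix` or `jaw_pcoa`) or a
#'   symmetric zero-diagonal distance matrix.
#' @param labels group label per specimen.
#' @param n_permutations Monte-Carlo permutation count (default 9999),
#'   or `"exhaustive"` to force full enumeration.
#' @param seed integer seed for the permutation stream (required for
#'   Monte-Carlo runs).
#' @param exhaustive_limit enumerate exactly when the number of
#'   distinct arrangements is at most this (default 1e5).
#' @return object of class `permanova_result`: `pseudo_F`, `p_raw`,
#'   `n_permutations` (draws or arrangements used), `method`
#'   (`"exhaustive"` or `"monte-carlo"`), `seed`, `groups_tested`,
#'   `df_between`, `df_within`.
#' @export
permanova_oneway <- function(x, labels, n_permutations = 9999,
                             seed = NULL, exhaustive_limit = 1e5) {
  d2 <- as_squared_distance(x)
  labels <- as.character(labels)
  n <- nrow(d2)
  if (length(labels) != n) stop("labels length must match specimen count")
  ## canonical specimen order for order-invariant permutation stream
  if (!is.null(rownames(d2))) {
    o <- order(rownames(d2))
    d2 <- d2[o, o, drop = FALSE]
    labels <- labels[o]
  }
  groups <- sort(unique(labels))
  counts <- as.integer(table(factor(labels, levels = groups)))
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(counts < 2)) {
    stop("each group needs at least 2 members; undersized: ",
         paste(groups[counts < 2], collapse = ", "))
  }
  g <- length(groups)
  lab_int <- match(labels, groups)
  ss_total <- sum(d2) / (2 * n)
  if (ss_total <= 0) stop("degenerate data: zero total sum of squares")
  f_obs <- pseudo_f(ss_total,
                    within_ss_batch(d2, matrix(lab_int, ncol = 1), counts),
                    n, g)

  n_arr <- n_arrangements(counts)
  exhaustive <- identical(n_permutations, "exhaustive") ||
    n_arr <= exhaustive_limit
  if (exhaustive) {
    if (n_arr > exhaustive_limit) {
      stop("exhaustive enumeration requested but ", format(n_arr),
           " arrangements exceed exhaustive_limit")
    }
    arr <- enumerate_arrangements(counts)
    f_all <- pseudo_f(ss_total, within_ss_batch(d2, arr, counts), n, g)
    p <- mean(f_all >= f_obs - 1e-12)
    nper <- ncol(arr)
    method <- "exhaustive"
  } else {
    if (is.null(seed)) stop("seed is required for Monte-Carlo permutations")
    set.seed(seed)
    nper <- as.integer(n_permutations)
    perm <- vapply(seq_len(nper), function(i) sample(lab_int),
                   integer(n))
    f_perm <- pseudo_f(ss_total, within_ss_batch(d2, perm, counts), n, g)
    p <- (sum(f_perm >= f_obs - 1e-12) + 1) / (nper + 1)
    method <- "monte-carlo"
  }
  structure(list(pseudo_F = f_obs, p_raw = p, n_permutations = nper,
                 method = method, seed = seed, groups_tested = groups,
                 df_between = g - 1, df_within = n - g),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA (%s, %d permutations): pseudo-F(%d, %d) = %.4f, p = %.4g\n",
    x$method, x$n_permutations, x$df_between, x$df_within,
    x$pseudo_F, x$p_raw))
  cat("  groups:", paste(x$groups_tested, collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise PERMANOVA with multiplicity correction
#'
#' Runs [permanova_oneway()] on every unordered pair of groups that
#' meets the minimum size, then adjusts the raw p-values with both the
#' Bonferroni and the Benjamini-Hochberg step-up procedures over the
#' number of completed comparisons.  Undersized groups are skipped with
#' a warning and recorded.
#'
#' @inheritParams permanova_oneway
#' @param min_group_size smallest group admitted to testing
#'   (default 3).
#' @return data frame of class `pairwise_permanova` with columns
#'   `group_A`, `group_B`, `statistic`, `p_raw`, `p_bonferroni`,
#'   `p_bh`, plus attributes `m` (number of comparisons), `skipped`.
#' @export
permanova_pairwise <- function(x, labels, n_permutations = 9999,
                               seed = NULL, min_group_size = 3,
                               exhaustive_limit = 1e5) {
  coords <- as.matrix(if (inherits(x, "jaw_pcoa")) x$coordinates else
                      if (inherits(x, "std_matrix")) x$values else x)
  labels <- as.character(labels)
  keep <- groups_testable(labels, min_group_size)
  skipped <- setdiff(sort(unique(labels)), keep)
  if (length(keep) < 2) stop("fewer than 2 testable groups")
  pairs <- utils::combn(sort(keep), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    sel <- labels %in% c(a, b)
    res <- permanova_oneway(coords[sel, , drop = FALSE], labels[sel],
                            n_permutations = n_permutations,
                            seed = if (is.null(seed)) NULL else seed + k,
                            exhaustive_limit = exhaustive_limit)
    data.frame(group_A = a, group_B = b, statistic = res$pseudo_F,
               p_raw = res$p_raw, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- stats::p.adjust(out$p_raw, "bonferroni")
  out$p_bh <- stats::p.adjust(out$p_raw, "BH")
  attr(out, "m") <- nrow(out)
  attr(out, "skipped") <- skipped
  class(out) <- c("pairwise_permanova", "data.frame")
  out
}

#' Pairwise table in square-matrix layout
#'
#' Reshapes a pairwise test table into the groups-by-groups matrix of
#' adjusted p-values conventionally printed for PERMANOVA results.
#'
#' @param x a `pairwise_permanova` data frame.
#' @param column which p-value column to place in the matrix.
#' @return symmetric numeric matrix with `NA` diagonal.
#' @export
pairwise_matrix <- function(x, column = "p_bonferroni") {
  groups <- sort(unique(c(x$group_A, x$group_B)))
  m <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (i in seq_len(nrow(x))) {
    m[x$group_A[i], x$group_B[i]] <- x[[column]][i]
    m[x$group_B[i], x$group_A[i]] <- x[[column]][i]
  }
  m
}
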