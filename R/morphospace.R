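#' Euclidean distance matrix between specimens
#'
#' @param x a `std_matrix` from [zscore_matrix()] or a plain numeric
#'   matrix (specimens x characters), no missing values.
#' @return symmetric numeric matrix of pairwise Euclidean distances
#'   with zero diagonal and specimen ids as dimnames.
#' @export
euclidean_distances <- function(x) {
  if (inherits(x, "std_matrix")) x <- x$values
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values: impute or remove rows first")
  d <- as.matrix(stats::dist(x, method = "euclidean"))
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Embeds a distance matrix by double-centering the squared distances,
#' `B = -1/2 J D^2 J` with `J` the centering projector, and
#' eigendecomposing `B`.  Coordinates are eigenvectors scaled by the
#' square root of their (positive) eigenvalues; axes are ordered by
#' descending eigenvalue with ties broken by original index.
#' Eigenvalues within `eps` of zero (relative to the largest) are
#' clamped to zero; variance-explained fractions are computed over the
#' positive eigenvalues.  Distances that are genuinely non-Euclidean
#' (negative eigenvalues beyond tolerance) abort with a diagnostic.
#'
#' Each retained axis is given a deterministic orientation: the
#' specimen with the largest absolute score on that axis scores
#' positive.  For Euclidean input the scores coincide (up to sign)
#' with principal-component scores of the original data matrix.
#'
#' @param d symmetric distance matrix (e.g. from
#'   [euclidean_distances()]).
#' @param n_axes number of axes to retain, or `"all"` (default) for
#'   every positive-eigenvalue axis.
#' @param eps relative tolerance for clamping near-zero eigenvalues.
#' @return object of class `jaw_pcoa`: list with `coordinates`
#'   (specimens x axes, columns `PCo1`, `PCo2`, ...), `eigenvalues`
#'   (all, descending), `variance_explained` (fractions over positive
#'   eigenvalues), `n_axes_retained`.
#' @export
pcoa <- function(d, n_axes = "all", eps = 1e-8) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("ordination needs at least 2 specimens")
  if (max(abs(d - t(d))) > 1e-10) stop("distance matrix is not symmetric")
  if (all(d == 0)) stop("degenerate ordination: all distances are zero")

  d2 <- d^2
  ## double centering without forming J explicitly
  rm_ <- rowMeans(d2); gm <- mean(d2)
  b <- -0.5 * (d2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  lambda <- e$values
  tol <- eps * max(abs(lambda))
  if (any(lambda < -tol)) {
    stop("distance matrix is not Euclidean-embeddable: negative ",
         "eigenvalue ", format(min(lambda)), " beyond tolerance")
  }
  lambda[abs(lambda) < tol] <- 0
  lambda[lambda < 0] <- 0
  ## eigen() returns descending order; equal values keep original order
  pos <- which(lambda > 0)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lambda[pos]),
                                                   length(pos))
  ## deterministic sign: largest-|score| specimen positive on each axis
  for (j in seq_len(ncol(coords))) {
    k <- which.max(abs(coords[, j]))
    if (coords[k, j] < 0) coords[, j] <- -coords[, j]
  }
  var_exp <- lambda[pos] / sum(lambda[pos])
  keep <- if (identical(n_axes, "all")) length(pos) else
    min(as.integer(n_axes), length(pos))
  coords <- coords[, seq_len(keep), drop = FALSE]
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(keep))
  structure(list(coordinates = coords,
                 eigenvalues = lambda,
                 variance_explained = var_exp,
                 n_axes_retained = keep),
            class = "jaw_pcoa")
}

#' @export
print.jaw_pcoa <- function(x, ...) {
  ve <- x$variance_explained
  k <- min(3, length(ve))
  cat("Principal coordinate ordination: ", nrow(x$coordinates),
      " specimens, ", x$n_axes_retained, " axes retained\n", sep = "")
  cat("  variance explained (first ", k, " axes): ",
      paste(sprintf("%.1f%%", 100 * ve[seq_len(k)]), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Morphospace scatter plot
#'
#' Two-axis scatter of PCo scores colored by a grouping label, using
#' base graphics.  Purely optional output; no analysis depends on it.
#'
#' @param ord a `jaw_pcoa` object.
#' @param groups vector of group labels, one per specimen.
#' @param axes length-2 integer vector of axes to plot.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, the plotted coordinates.
#' @export
plot_morphospace <- function(ord, groups, axes = c(1, 2), ...) {
  stopifnot(inherits(ord, "jaw_pcoa"), length(axes) == 2)
  xy <- ord$coordinates[, axes, drop = FALSE]
  g <- factor(groups)
  ve <- 100 * ord$variance_explained[axes]
  graphics::plot(xy, col = as.integer(g), pch = 19,
                 xlab = sprintf("PCo%d (%.1f%%)", axes[1], ve[1]),
                 ylab = sprintf("PCo%d (%.1f%%)", axes[2], ve[2]), ...)
  graphics::legend("topright", legend = levels(g), col = seq_along(levels(g)),
                   pch = 19, cex = 0.8)
  invisible(xy)
}
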