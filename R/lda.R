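## Gaussian linear discriminant fit with pooled within-class
## covariance and equal priors.  A small ridge (lambda on the
## diagonal, scaled to mean diagonal magnitude) is added automatically
## when the pooled covariance is numerically singular; the lambda used
## is recorded so regularization is never silent.
lda_pooled_fit <- function(x, y, ridge = 1e-6) {
  x <- as.matrix(x)
  y <- factor(y)
  classes <- levels(y)
  p <- ncol(x)
  n <- nrow(x)
  means <- t(vapply(classes, function(cl)
    colMeans(x[y == cl, , drop = FALSE]), numeric(p)))
  centered <- x - means[as.integer(y), , drop = FALSE]
  sp <- crossprod(centered) / (n - length(classes))
  lambda <- 0
  sp_inv <- tryCatch({
    if (rcond(sp) < 1e-10) stop("near-singular")
    solve(sp)
  }, error = function(e) NULL)
  if (is.null(sp_inv)) {
    lambda <- ridge * mean(diag(sp))
    for (k in 1:8) {
      sp_inv <- tryCatch(solve(sp + lambda * diag(p)),
                         error = function(e) NULL)
      if (!is.null(sp_inv) && rcond(sp + lambda * diag(p)) > 1e-12) break
      lambda <- lambda * 10
    }
    if (is.null(sp_inv)) {
      stop("pooled within-class covariance is singular even after ",
           "ridge regularization")
    }
    message("lda: ridge regularization applied, lambda = ",
            format(lambda))
  }
  ## discriminant weights: W = Sp^-1 M', intercepts -0.5 diag(M Sp^-1 M')
  w <- sp_inv %*% t(means)
  b <- -0.5 * colSums(t(means) * w)
  list(classes = classes, means = means, pooled_cov = sp,
       weights = w, intercepts = b, lambda = lambda)
}

lda_pooled_predict <- function(fit, newx) {
  newx <- matrix(newx, ncol = nrow(fit$weights))
  scores <- newx %*% fit$weights +
    matrix(fit$intercepts, nrow(newx), length(fit$intercepts),
           byrow = TRUE)
  fit$classes[max.col(scores, ties.method = "first")]
}

#' Jackknifed (leave-one-out) linear discriminant classification
#'
#' For every specimen, fits a multi-class linear discriminant model
#' (pooled within-class covariance, equal priors) on the remaining
#' specimens and predicts the held-out one; aggregates the predictions
#' into a confusion matrix and correct-classification rates.  This is
#' the standard jackknifed estimate of how well the morphofunctional
#' characters predict clade or guild membership.
#'
#' @param x feature matrix: a `std_matrix`, a `jaw_pcoa` (its
#'   coordinates), or a plain numeric matrix.
#' @param labels class label per specimen.
#' @param feature_set descriptive tag stored on the result
#'   (`"characters"` or `"pco_scores"`).
#' @param min_class_size classes smaller than this are excluded with a
#'   warning (default 3).
#' @return object of class `lda_result`: `confusion_matrix` (true
#'   class by predicted class counts), `overall_jackknife_rate`,
#'   `per_class_rates`, `feature_set`, `n`.
#' @export
lda_jackknife <- function(x, labels, feature_set = "characters",
                          min_class_size = 3) {
  x <- as.matrix(if (inherits(x, "jaw_pcoa")) x$coordinates else
                 if (inherits(x, "std_matrix")) x$values else x)
  labels <- as.character(labels)
  keep_classes <- groups_testable(labels, min_class_size)
  if (length(keep_classes) < 2) stop("need at least 2 testable classes")
  sel <- labels %in% keep_classes
  x <- x[sel, , drop = FALSE]
  y <- factor(labels[sel], levels = sort(keep_classes))
  n <- nrow(x)
  if (ncol(x) >= n - length(keep_classes)) {
    warning("feature count approaches residual degrees of freedom; ",
            "ridge regularization may engage", call. = FALSE)
  }
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- lda_pooled_fit(x[-i, , drop = FALSE], y[-i])
    sc <- drop(x[i, ] %*% fit$weights) + fit$intercepts
    pred[i] <- fit$classes[which.max(sc)]
  }
  cm <- table(true = y, predicted = factor(pred, levels = levels(y)))
  overall <- sum(diag(cm)) / n
  per_class <- diag(cm) / rowSums(cm)
  structure(list(confusion_matrix = cm,
                 overall_jackknife_rate = overall,
                 per_class_rates = per_class,
                 feature_set = feature_set, n = n),
            class = "lda_result")
}

#' @export
print.lda_result <- function(x, ...) {
  cat(sprintf(
    "Jackknifed LDA (%s, n = %d): %.1f%% correctly classified\n",
    x$feature_set, x$n, 100 * x$overall_jackknife_rate))
  print(x$confusion_matrix)
  invisible(x)
}
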