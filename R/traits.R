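## default metric families for direct comparisons: morphology
## (size, robustness, tooth size) and function (input force, force
## transmission at the largest tooth, opening speed)
JAW_MORPHO_METRICS <- c("ML", "MSL.ML", "MSD.ML", "CPD.ML", "TI")
JAW_FUNCTION_METRICS <- c("maL.ML", "ltMA", "oMA")

#' Per-specimen metric table for direct comparisons
#'
#' Computes the selected morphological (`ML`, `MSL.ML`, `MSD.ML`,
#' `CPD.ML`, `TI`) and functional (`maL.ML`, `ltMA`, `oMA`) metrics
#' for every specimen.  `ML` is returned on the log scale by default
#' because jaw lengths span roughly an order of magnitude; `ltMA` is
#' `NA` for specimens lacking the largest-tooth position `DLT`.
#'
#' @param table an `assemblage` object.
#' @param metrics metric names to include.
#' @param log_ml compare `ML` on the natural-log scale (default
#'   `TRUE`).
#' @return numeric matrix, specimen ids as row names.
#' @export
metric_table <- function(table,
                         metrics = c(JAW_MORPHO_METRICS,
                                     JAW_FUNCTION_METRICS),
                         log_ml = TRUE) {
  full <- character_matrix(table, characters = c(JAW_CHARACTERS,
                                                 "ltMA", "ML"))
  if (log_ml && "ML" %in% metrics) full[, "ML"] <- log(full[, "ML"])
  full[, metrics, drop = FALSE]
}

#' Pairwise univariate group comparisons of jaw metrics
#'
#' For every metric and every unordered pair of groups with at least
#' `min_n` non-missing values each, runs a Welch two-sample t-test and
#' a Wilcoxon rank-sum test (exact when both groups have at most 12
#' values and no ties; normal approximation with tie correction
#' otherwise).  Bonferroni correction is applied within each metric's
#' family of pairwise comparisons.
#'
#' @inheritParams metric_table
#' @param grouping label system: `"clade"`, `"guild"` or `"time_bin"`.
#' @param min_n minimum non-missing group size per pair (default 3).
#' @param merge_pierce collapse Pierce I/II into one guild first.
#' @return data frame of class `metric_comparison` with columns
#'   `metric`, `group_A`, `group_B`, `test`, `statistic`, `p_raw`,
#'   `p_bonferroni`; attribute `grouping_system` records the label
#'   system, attribute `skipped` the pairs dropped for size.
#' @export
pairwise_metric_tests <- function(table,
                                  metrics = c(JAW_MORPHO_METRICS,
                                              JAW_FUNCTION_METRICS),
                                  grouping = c("clade", "guild",
                                               "time_bin"),
                                  min_n = 3, log_ml = TRUE,
                                  merge_pierce = FALSE) {
  grouping <- match.arg(grouping)
  mt <- metric_table(table, metrics, log_ml = log_ml)
  labels <- table$records[[grouping]]
  if (merge_pierce && grouping == "guild") labels <- collapse_pierce(labels)
  groups <- sort(unique(labels))
  skipped <- character(0)
  out <- list()
  for (metric in metrics) {
    v <- mt[, metric]
    sizes <- vapply(groups, function(g)
      sum(!is.na(v[labels == g])), integer(1))
    ok <- groups[sizes >= min_n]
    if (length(ok) < 2) next
    pairs <- utils::combn(ok, 2)
    rows <- list()
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      xa <- v[labels == a & !is.na(v)]
      xb <- v[labels == b & !is.na(v)]
      tt <- tryCatch(stats::t.test(xa, xb, var.equal = FALSE),
                     error = function(e) {
                       # zero-variance groups: identical means are a
                       # null result, distinct means a total separation
                       if (isTRUE(all.equal(mean(xa), mean(xb)))) {
                         list(statistic = c(t = 0), p.value = 1)
                       } else {
                         list(statistic = c(t = sign(mean(xa) -
                                                       mean(xb)) * Inf),
                              p.value = 0)
                       }
                     })
      use_exact <- length(xa) <= 12 && length(xb) <= 12 &&
        !any(duplicated(c(xa, xb)))
      wt <- suppressWarnings(
        stats::wilcox.test(xa, xb, exact = use_exact, correct = TRUE))
      rows[[k]] <- data.frame(
        metric = metric, group_A = a, group_B = b,
        test = c("t", "wilcoxon"),
        statistic = c(unname(tt$statistic), unname(wt$statistic)),
        p_raw = c(tt$p.value, wt$p.value),
        stringsAsFactors = FALSE)
    }
    fam <- do.call(rbind, rows)
    m <- ncol(pairs)  # per-metric family of pairwise comparisons
    fam$p_bonferroni <- pmin(1, fam$p_raw * m)
    out[[metric]] <- fam
    skipped <- c(skipped, if (length(ok) < length(groups))
      paste0(metric, ":", paste(setdiff(groups, ok), collapse = "/")))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "grouping_system") <- grouping
  attr(res, "skipped") <- skipped
  class(res) <- c("metric_comparison", "data.frame")
  res
}

#' Standardized species-by-metric matrix for comparative heatmaps
#'
#' Z-standardizes each metric across all included specimens and
#' returns the matrix in a caller-supplied row order (typically an
#' informal phylogenetic ordering), ready for heatmap plotting.
#'
#' @inheritParams metric_table
#' @param row_order character vector of specimen ids giving the row
#'   order; defaults to table order.
#' @return numeric matrix with attribute `row_order_provenance`.
#' @export
standardized_metric_matrix <- function(table,
                                       metrics = c(JAW_MORPHO_METRICS,
                                                   JAW_FUNCTION_METRICS),
                                       row_order = NULL,
                                       log_ml = TRUE) {
  mt <- metric_table(table, metrics, log_ml = log_ml)
  if (anyNA(mt)) {
    drop_cols <- colnames(mt)[colSums(is.na(mt)) > 0]
    warning("metric(s) with missing values dropped: ",
            paste(drop_cols, collapse = ", "), call. = FALSE)
    mt <- mt[, setdiff(colnames(mt), drop_cols), drop = FALSE]
  }
  z <- zscore_matrix(mt)$values
  if (is.null(row_order)) {
    prov <- "table order"
  } else {
    if (!setequal(row_order, rownames(z)) ||
        length(row_order) != nrow(z)) {
      stop("row_order must be a permutation of the specimen ids")
    }
    z <- z[row_order, , drop = FALSE]
    prov <- "user-supplied"
  }
  attr(z, "row_order_provenance") <- prov
  z
}
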