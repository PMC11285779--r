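#' Configure the full analysis pipeline
#'
#' @param input path to a specimen CSV, an `assemblage`, or a
#'   `simulation_config` (the table is then simulated).
#' @param groupings label systems to test (subset of `"clade"`,
#'   `"guild"`).
#' @param merge_pierce analyse guilds with Pierce I/II merged.
#' @param time_bin_comparisons run within-group disparity comparisons
#'   between the two time bins where sample sizes allow.
#' @param n_permutations,n_bootstrap resampling effort.
#' @param min_group_size smallest group admitted to inferential tests.
#' @param seed integer seed (mandatory); stage seeds are derived from
#'   it deterministically.
#' @param out_dir output directory for the CSV results bundle and JSON
#'   manifest, or `NULL` to skip writing.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, groupings = c("clade", "guild"),
                            merge_pierce = FALSE,
                            time_bin_comparisons = TRUE,
                            n_permutations = 9999, n_bootstrap = 1000,
                            min_group_size = 3, seed, out_dir = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  groupings <- match.arg(groupings, c("clade", "guild"),
                         several.ok = TRUE)
  structure(list(input = input, groupings = groupings,
                 merge_pierce = merge_pierce,
                 time_bin_comparisons = time_bin_comparisons,
                 n_permutations = n_permutations,
                 n_bootstrap = n_bootstrap,
                 min_group_size = min_group_size,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full morphofunctional analysis pipeline
#'
#' End-to-end orchestration: load or simulate the specimen table,
#' compute the character matrix, z-score it, build the Euclidean
#' distance matrix and PCo ordination, then for each requested label
#' system run one-way and pairwise PERMANOVA, the disparity analysis
#' (sum of variances, bootstrap intervals, permutation and rank-sum
#' tests), jackknifed LDA, and the univariate metric comparisons.
#' Optionally compares within-group disparity between the two time
#' bins where both bins have enough specimens, skipping cleanly (with
#' a log message) where they do not.  With `out_dir` set, writes every
#' table as CSV plus a JSON manifest holding parameters, seeds and an
#' md5 hash of every file; two runs with the same configuration and
#' seed produce identical manifests.
#'
#' @param config a `pipeline_config`.
#' @param quiet suppress progress messages.
#' @return a list (class `pipeline_result`) with elements `table`,
#'   `composition`, `characters`, `standardized`, `distances`,
#'   `ordination`, `by_grouping` (per label system: `permanova`,
#'   `pairwise_permanova`, `disparity`, `lda`, `metric_tests`),
#'   `time_bin`, `heatmap_matrix`, `manifest`.
#' @export
run_full_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[jawspace] ", ...)

  table <- config$input
  if (inherits(table, "simulation_config")) {
    say("simulating assemblage (seed ", table$seed, ")")
    table <- simulate_assemblage(table)
  } else if (is.character(table)) {
    say("reading specimen table: ", table)
    table <- read_specimen_table(table)
  }
  stopifnot(inherits(table, "assemblage"))

  chars <- character_matrix(table)
  std <- zscore_matrix(chars)
  d <- euclidean_distances(std)
  ord <- pcoa(d)
  say(sprintf("ordination: %d axes, first three explain %.1f%%",
              ord$n_axes_retained,
              100 * sum(ord$variance_explained[1:min(3,
                length(ord$variance_explained))])))

  by_grouping <- list()
  for (grouping in config$groupings) {
    labels <- table$records[[grouping]]
    if (grouping == "guild" && config$merge_pierce) {
      labels <- collapse_pierce(labels)
    }
    labels <- ifelse(labels == "Unassigned", NA, labels)
    sel <- !is.na(labels)
    say("testing grouping: ", grouping)
    res <- list()
    res$permanova <- permanova_oneway(
      ord$coordinates[sel, , drop = FALSE], labels[sel],
      n_permutations = config$n_permutations, seed = config$seed + 11)
    res$pairwise_permanova <- permanova_pairwise(
      ord$coordinates[sel, , drop = FALSE], labels[sel],
      n_permutations = config$n_permutations, seed = config$seed + 23,
      min_group_size = config$min_group_size)
    res$disparity <- disparity_analysis(
      ord$coordinates[sel, , drop = FALSE], labels[sel],
      n_bootstrap = config$n_bootstrap,
      n_permutations = config$n_permutations, seed = config$seed + 37,
      min_group_size = config$min_group_size)
    res$lda <- lda_jackknife(std$values[sel, , drop = FALSE],
                             labels[sel], feature_set = "characters",
                             min_class_size = config$min_group_size)
    res$metric_tests <- pairwise_metric_tests(
      table, grouping = grouping, min_n = config$min_group_size,
      merge_pierce = config$merge_pierce)
    by_grouping[[grouping]] <- res
  }

  time_bin <- NULL
  if (config$time_bin_comparisons) {
    time_bin <- compare_time_bins(table, ord, config, say)
  }

  heat <- suppressWarnings(standardized_metric_matrix(table))

  result <- list(table = table,
                 composition = summarize_composition(table),
                 characters = chars, standardized = std, distances = d,
                 ordination = ord, by_grouping = by_grouping,
                 time_bin = time_bin, heatmap_matrix = heat,
                 config = config, manifest = NULL)
  if (!is.null(config$out_dir)) {
    result$manifest <- write_results_bundle(result, config$out_dir)
  }
  class(result) <- "pipeline_result"
  result
}

## within-group disparity comparison between the two time bins;
## groups with fewer than min members in either bin are skipped
compare_time_bins <- function(table, ord, config, say) {
  df <- table$records
  bins <- JAW_TIME_BINS
  out <- list()
  for (grouping in config$groupings) {
    labels <- df[[grouping]]
    for (g in sort(unique(labels))) {
      n_bin <- vapply(bins, function(b)
        sum(labels == g & df$time_bin == b), integer(1))
      if (any(n_bin < max(2, config$min_group_size - 1))) {
        say("time-bin comparison skipped for ", g,
            " (bin sizes ", paste(n_bin, collapse = "/"), ")")
        next
      }
      pt <- disparity_permutation_test(
        ord$coordinates,
        which(labels == g & df$time_bin == bins[1]),
        which(labels == g & df$time_bin == bins[2]),
        n_permutations = config$n_permutations,
        seed = config$seed + 51)
      out[[paste(grouping, g, sep = ":")]] <- data.frame(
        grouping = grouping, group = g,
        n_ocf = n_bin[1], n_kcf = n_bin[2],
        sov_ocf = pt$sov_a, sov_kcf = pt$sov_b,
        difference = pt$observed_difference, p = pt$p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

## CSV results bundle + JSON manifest with md5 hashes
write_results_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(obj, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(obj), path, row.names = TRUE)
    files <<- c(files, path)
  }
  write_specimen_table(result$table, file.path(out_dir, "specimens.csv"))
  files <- file.path(out_dir, "specimens.csv")
  put(result$characters, "characters.csv")
  put(result$ordination$coordinates, "pco_scores.csv")
  put(data.frame(eigenvalue = result$ordination$eigenvalues),
      "pco_eigenvalues.csv")
  for (grouping in names(result$by_grouping)) {
    res <- result$by_grouping[[grouping]]
    put(res$pairwise_permanova,
        paste0("permanova_pairwise_", grouping, ".csv"))
    put(pairwise_matrix(res$pairwise_permanova),
        paste0("permanova_matrix_", grouping, ".csv"))
    put(res$disparity$per_group, paste0("disparity_", grouping, ".csv"))
    put(res$disparity$pairwise,
        paste0("disparity_pairwise_", grouping, ".csv"))
    put(as.data.frame.matrix(res$lda$confusion_matrix),
        paste0("lda_confusion_", grouping, ".csv"))
    put(res$metric_tests, paste0("metric_tests_", grouping, ".csv"))
  }
  if (!is.null(result$time_bin)) put(result$time_bin, "time_bins.csv")
  put(result$heatmap_matrix, "heatmap_matrix.csv")

  manifest <- list(
    package = "jawspace",
    version = as.character(utils::packageVersion("jawspace")),
    seed = result$config$seed,
    parameters = result$config[c("groupings", "merge_pierce",
                                 "time_bin_comparisons",
                                 "n_permutations", "n_bootstrap",
                                 "min_group_size")],
    provenance = result$table$provenance,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) list(md5 = unname(tools::md5sum(f)))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("jawspace pipeline result\n")
  print(x$composition)
  print(x$ordination)
  for (g in names(x$by_grouping)) {
    cat("--", g, "--\n")
    print(x$by_grouping[[g]]$permanova)
    print(x$by_grouping[[g]]$lda)
  }
  invisible(x)
}
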