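#' Read and validate a specimen measurement table
#'
#' Reads a CSV of raw mandibular measurements (mm) plus categorical
#' metadata and validates every row against the measurement invariants:
#' all present values strictly positive; `MSL`, `TRL`, `RPL` and `maL`
#' each smaller than the total mandibular length `ML`; `DLT` (distance
#' from the anterior tip to the largest tooth), when present, smaller
#' than the pre-fulcrum jaw length `ML - RPL`.  Categorical labels are
#' normalized for case and surrounding whitespace and checked against
#' the fixed vocabularies (see [coarsen_clade()] for the clade system).
#'
#' @param path path to a CSV file with the canonical columns
#'   (`specimen_id`, `taxon`, `clade`, `sublineage`, `guild`,
#'   `time_bin`, the thirteen measurement columns, `source_note`).
#' @param coerce_unknown if `TRUE`, unknown clade/guild/time-bin labels
#'   are mapped to `"Unassigned"` (excluded from inferential tests
#'   downstream) instead of raising an error.
#' @return an object of class `assemblage`, a list with elements
#'   `records` (a validated `data.frame`, one row per specimen) and
#'   `provenance` (the file path, or `"synthetic:<seed>"` for simulated
#'   tables).
#' @seealso [write_specimen_table()], [summarize_composition()],
#'   [simulate_assemblage()]
#' @export
read_specimen_table <- function(path, coerce_unknown = FALSE) {
  if (!file.exists(path)) {
    stop("specimen table not found: ", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(JAW_TABLE_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("specimen table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, JAW_TABLE_COLUMNS]
  for (m in JAW_MEASUREMENTS) {
    df[[m]] <- suppressWarnings(as.numeric(ifelse(df[[m]] == "", NA, df[[m]])))
  }
  as_assemblage(df, provenance = path, coerce_unknown = coerce_unknown)
}

#' Construct a validated assemblage from a data frame
#'
#' @param df data frame with the canonical specimen-table columns.
#' @param provenance provenance string recorded on the result.
#' @inheritParams read_specimen_table
#' @return an `assemblage` object.
#' @export
as_assemblage <- function(df, provenance = "in-memory",
                          coerce_unknown = FALSE) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("specimen_id", "taxon", "clade", "sublineage", "guild",
                "time_bin", "source_note")) {
    if (is.null(df[[col]])) df[[col]] <- ""
    df[[col]] <- trimws(as.character(df[[col]]))
    df[[col]][is.na(df[[col]])] <- ""
  }
  df <- df[, JAW_TABLE_COLUMNS]

  if (nrow(df) < 1) stop("assemblage must contain at least one record")
  dup <- df$specimen_id[duplicated(df$specimen_id)]
  if (length(dup)) {
    stop("duplicate specimen_id: ", paste(unique(dup), collapse = ", "))
  }
  if (any(df$specimen_id == "")) stop("empty specimen_id")

  df$clade <- normalize_label(df$clade, JAW_CLADES, "clade", coerce_unknown)
  df$guild <- normalize_label(df$guild, JAW_GUILDS, "guild", coerce_unknown)
  df$time_bin <- normalize_label(df$time_bin, JAW_TIME_BINS, "time_bin",
                                 coerce_unknown)

  for (i in seq_len(nrow(df))) {
    validate_measurements(df[i, JAW_MEASUREMENTS], df$specimen_id[i])
  }

  structure(list(records = df, provenance = provenance),
            class = "assemblage")
}

## case/whitespace-insensitive matching against a fixed vocabulary
normalize_label <- function(x, vocab, what, coerce_unknown) {
  idx <- match(tolower(x), tolower(vocab))
  out <- vocab[idx]
  bad <- is.na(idx)
  if (any(bad)) {
    if (coerce_unknown) {
      out[bad] <- "Unassigned"
    } else {
      stop("unknown ", what, " label(s): ",
           paste(unique(x[bad]), collapse = ", "),
           " (expected one of: ", paste(vocab, collapse = ", "), ")")
    }
  }
  out
}

validate_measurements <- function(m, specimen_id) {
  m <- as.list(m)
  req_missing <- JAW_MEASUREMENTS_REQUIRED[
    vapply(m[JAW_MEASUREMENTS_REQUIRED], function(v) is.na(v), logical(1))]
  if (length(req_missing)) {
    stop("specimen ", specimen_id, ": missing required measurement(s): ",
         paste(req_missing, collapse = ", "))
  }
  present <- JAW_MEASUREMENTS[!vapply(m[JAW_MEASUREMENTS], is.na, logical(1))]
  nonpos <- present[vapply(m[present], function(v) v <= 0, logical(1))]
  if (length(nonpos)) {
    stop("specimen ", specimen_id, ": non-positive measurement(s): ",
         paste(nonpos, collapse = ", "))
  }
  for (f in c("MSL", "TRL", "RPL", "maL")) {
    if (m[[f]] >= m$ML) {
      stop("specimen ", specimen_id, ": ", f, " < ML violated (",
           f, " = ", m[[f]], ", ML = ", m$ML, ")")
    }
  }
  if (!is.na(m$DLT) && m$DLT >= m$ML - m$RPL) {
    stop("specimen ", specimen_id,
         ": DLT < ML - RPL violated (largest tooth behind the fulcrum)")
  }
  invisible(TRUE)
}

#' Write a specimen table to CSV
#'
#' Writes the canonical column order with a header row.  Missing
#' optional measurements and empty note fields are written as empty
#' cells; a write followed by [read_specimen_table()] reproduces the
#' table record for record, and a second write is byte-identical.
#'
#' @param table an `assemblage` object.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_specimen_table <- function(table, path) {
  stopifnot(inherits(table, "assemblage"))
  df <- table$records
  num <- df[, JAW_MEASUREMENTS, drop = FALSE]
  out <- df
  for (m in JAW_MEASUREMENTS) {
    v <- format(num[[m]], digits = 15, trim = TRUE, scientific = FALSE)
    v[is.na(num[[m]])] <- ""
    out[[m]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = which(
    names(out) %in% c("specimen_id", "taxon", "clade", "sublineage",
                      "guild", "time_bin", "source_note")), na = "")
  invisible(path)
}

#' Tabulate assemblage composition
#'
#' Counts of specimens per clade (fine and family-rank), feeding guild
#' and time bin.  Every vocabulary level is listed, including empty
#' ones; each label system's counts sum to the number of records.
#'
#' @param table an `assemblage` object.
#' @return a list of named integer vectors (`clade`, `clade_coarse`,
#'   `guild`, `time_bin`) plus `n_total`, of class
#'   `assemblage_composition`.
#' @export
summarize_composition <- function(table) {
  stopifnot(inherits(table, "assemblage"))
  df <- table$records
  tab <- function(x, levels) {
    table(factor(x, levels = unique(c(levels, unique(x)))))
  }
  out <- list(
    n_total = nrow(df),
    clade = tab(df$clade, JAW_CLADES),
    clade_coarse = tab(coarsen_clade(df$clade),
                       unique(coarsen_clade(JAW_CLADES))),
    guild = tab(df$guild, JAW_GUILDS),
    time_bin = tab(df$time_bin, JAW_TIME_BINS)
  )
  class(out) <- "assemblage_composition"
  out
}

#' @export
print.assemblage_composition <- function(x, ...) {
  cat("Assemblage composition:", x$n_total, "specimens\n")
  for (sys in c("clade", "guild", "time_bin")) {
    cat("  by ", sys, ": ",
        paste(names(x[[sys]]), as.integer(x[[sys]]), sep = "=",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.assemblage <- function(x, ...) {
  cat("Assemblage of", nrow(x$records), "specimens (",
      x$provenance, ")\n")
  invisible(x)
}

#' Flag groups too small for inferential tests
#'
#' Groups below `min_n` members are carried through ordination but are
#' skipped (with a warning) by the PERMANOVA, LDA and disparity stages,
#' reflecting the reality of small fossil samples.
#'
#' @param labels vector of group labels.
#' @param min_n minimum group size for inclusion (default 3).
#' @return character vector of labels of groups meeting the threshold.
#' @export
groups_testable <- function(labels, min_n = 3) {
  tab <- table(labels)
  small <- names(tab)[tab < min_n]
  if (length(small)) {
    warning("group(s) below minimum size ", min_n,
            " skipped in inferential tests: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  names(tab)[tab >= min_n]
}
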