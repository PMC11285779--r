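#' Derive lever arms from raw jaw measurements
#'
#' Models the lower jaw as a third-class lever with the fulcrum at the
#' articular glenoid, located `RPL` (retroarticular process length)
#' from the posterior end of the ramus.  Out-levers are straight-line
#' distances along the jaw's long axis:
#'
#' * `out_anterior` = `ML - RPL` (fulcrum to anterior tip);
#' * `out_posterior_toothrow` = `out_anterior - TRL`, with the tooth
#'   row taken to begin at the anterior tip;
#' * `out_largest_tooth` = `out_anterior - DLT` when `DLT` (tip to
#'   largest tooth) is available, `NA` otherwise.
#'
#' The closing in-lever defaults to the adductor insertion length
#' `maL` — the measurable proxy for adductor moment arm in fossils —
#' unless an explicit `ILc` override is supplied.  The opening in-lever
#' is `RPL`, the depressor moment arm behind the fulcrum.
#'
#' @param m one-row data frame, named list or named vector of raw
#'   measurements (mm); requires `ML`, `RPL`, `TRL` and either `maL`
#'   or `ILc`; `DLT` optional.
#' @return named list with the five lever arms (mm).
#' @export
#' @examples
#' derive_lever_arms(list(ML = 1000, RPL = 100, TRL = 550,
#'                        DLT = 450, maL = 200, ILc = 150))
derive_lever_arms <- function(m) {
  m <- as.list(m)
  get <- function(f) if (is.null(m[[f]]) || length(m[[f]]) == 0) NA_real_ else as.numeric(m[[f]])
  ML <- get("ML"); RPL <- get("RPL"); TRL <- get("TRL")
  DLT <- get("DLT"); ILc <- get("ILc"); maL <- get("maL")
  if (any(is.na(c(ML, RPL, TRL)))) {
    stop("lever derivation requires ML, RPL and TRL")
  }
  out_ant <- ML - RPL
  out_post <- out_ant - TRL
  if (out_post <= 0) {
    stop("geometry error: tooth row (TRL = ", TRL,
         ") is not shorter than the pre-fulcrum jaw (ML - RPL = ",
         out_ant, ")")
  }
  in_clo <- if (!is.na(ILc)) ILc else maL
  if (is.na(in_clo)) stop("closing in-lever unavailable: need maL or ILc")
  if (in_clo <= 0) stop("geometry error: non-positive closing in-lever")
  out_lt <- if (!is.na(DLT)) out_ant - DLT else NA_real_
  if (!is.na(out_lt) && out_lt <= 0) {
    stop("geometry error: largest tooth lies at or behind the fulcrum")
  }
  list(fulcrum_offset = RPL,
       out_anterior = out_ant,
       out_posterior_toothrow = out_post,
       out_largest_tooth = out_lt,
       in_closing = in_clo,
       in_opening = RPL)
}

#' Compute the morphofunctional character vector for one jaw
#'
#' Returns the eleven dimensionless characters used in the morphospace
#' plus auxiliaries: seven measurements rescaled to mandibular length
#' (`ASD.ML`, `MSL.ML`, `MSD.ML`, `TRL.ML`, `CPD.ML`, `RPL.ML`,
#' `maL.ML`), the tooth index `TI = LCH/ML`, and four lever ratios —
#'
#' * `aMA`  = closing in-lever / anterior out-lever (anterior
#'   mechanical advantage);
#' * `pMA`  = closing in-lever / posterior-tooth-row out-lever;
#' * `ltMA` = closing in-lever / largest-tooth out-lever (bite point at
#'   the largest tooth; `NA` without `DLT`), an auxiliary not part of
#'   the 11-character morphospace set;
#' * `oMA`  = opening in-lever / anterior out-lever, so that low `oMA`
#'   means a fast-opening jaw.
#'
#' `ML` itself is retained separately as the size metric; every
#' character is invariant to uniform scaling of the jaw.
#'
#' @inheritParams derive_lever_arms
#' @return named numeric vector: the 11 characters (in canonical
#'   order), `ltMA` and `ML`.
#' @export
#' @examples
#' compute_characters(list(ML = 1000, ASD = 150, MSL = 300, MSD = 80,
#'                         TRL = 550, CPD = 120, RPL = 100, maL = 200,
#'                         LCH = 40, DLT = 450, ILc = 150))
compute_characters <- function(m) {
  m <- as.list(m)
  lv <- derive_lever_arms(m)
  ML <- as.numeric(m$ML)
  ratio <- function(f) as.numeric(m[[f]]) / ML
  out <- c(
    ASD.ML = ratio("ASD"), MSL.ML = ratio("MSL"), MSD.ML = ratio("MSD"),
    TRL.ML = ratio("TRL"), CPD.ML = ratio("CPD"), RPL.ML = ratio("RPL"),
    TI = ratio("LCH"), maL.ML = ratio("maL"),
    aMA = lv$in_closing / lv$out_anterior,
    pMA = lv$in_closing / lv$out_posterior_toothrow,
    oMA = lv$in_opening / lv$out_anterior,
    ltMA = if (is.na(lv$out_largest_tooth)) NA_real_ else
      lv$in_closing / lv$out_largest_tooth,
    ML = ML
  )
  out
}

#' Character matrix for an assemblage
#'
#' Applies [compute_characters()] to every record and assembles the
#' specimens-by-characters matrix.
#'
#' @param table an `assemblage` object.
#' @param characters which columns to return; defaults to the 11
#'   morphospace characters.  Use `c(JAW_CHARACTERS, "ltMA", "ML")`
#'   for the full set.
#' @return numeric matrix with specimen ids as row names.
#' @export
character_matrix <- function(table, characters = JAW_CHARACTERS) {
  stopifnot(inherits(table, "assemblage"))
  df <- table$records
  rows <- lapply(seq_len(nrow(df)), function(i) {
    compute_characters(df[i, JAW_MEASUREMENTS])
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- df$specimen_id
  mat[, characters, drop = FALSE]
}

#' Z-score a character matrix
#'
#' Centers and scales every column to sample mean 0 and sample
#' standard deviation 1 (denominator `n - 1`), recording the column
#' means and standard deviations so the transform can be inverted.
#' Constant columns are rejected rather than silently zeroed.
#'
#' @param x numeric matrix (specimens x characters) with at least two
#'   rows.
#' @return object of class `std_matrix`: a list with `values` (the
#'   standardized matrix), `center` and `scale`.
#' @export
zscore_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("z-scoring requires at least 2 specimens")
  if (anyNA(x)) {
    bad <- colnames(x)[colSums(is.na(x)) > 0]
    stop("missing values in character(s): ", paste(bad, collapse = ", "),
         "; impute or drop before standardizing")
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  if (any(const)) {
    stop("constant character column(s) cannot be z-scored: ",
         paste(colnames(x)[const], collapse = ", "))
  }
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  structure(list(values = z, center = mu, scale = sdv),
            class = "std_matrix")
}

#' Invert a z-score transform
#'
#' @param std a `std_matrix` object.
#' @param z optional matrix of standardized values to back-transform;
#'   defaults to `std$values`.
#' @return matrix on the original character scale.
#' @export
unscale_matrix <- function(std, z = std$values) {
  stopifnot(inherits(std, "std_matrix"))
  sweep(sweep(z, 2, std$scale, "*"), 2, std$center, "+")
}

#' @export
print.std_matrix <- function(x, ...) {
  cat("Standardized character matrix:", nrow(x$values), "specimens x",
      ncol(x$values), "characters\n")
  invisible(x)
}
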