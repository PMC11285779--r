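#' Label vocabularies and table schema
#'
#' Fixed vocabularies for the three label systems used throughout the
#' package (phylogenetic clade, tooth-based feeding guild, time bin) and
#' the canonical column layout of a specimen table.
#'
#' The clade vocabulary works at family/subfamily rank; the coarser
#' Metriorhynchidae alias pools Metriorhynchinae and Geosaurinae.  Feeding
#' guilds follow the six-guild tooth-based system (Cut, Generalist,
#' Pierce I, Pierce II, Smash, Crunch); the two Pierce guilds can be
#' merged on demand with [collapse_pierce()].  Time bins are the two
#' time-averaged assemblages, Oxford Clay Formation (OCF) and Kimmeridge
#' Clay Formation (KCF).
#'
#' @name jaw_vocab
#' @keywords internal
NULL

JAW_CLADES <- c("Pliosauridae", "Plesiosauroidea", "Metriorhynchinae",
                "Geosaurinae", "Teleosauroidea", "Ophthalmosauridae")

JAW_GUILDS <- c("Cut", "Generalist", "Pierce I", "Pierce II",
                "Smash", "Crunch")

JAW_TIME_BINS <- c("OCF", "KCF")

## measurement columns: required first, optional after LCH
JAW_MEASUREMENTS <- c("ML", "ASD", "MSL", "MSD", "TRL", "CPD", "RPL",
                      "maL", "LCH", "DLT", "ILc", "eTRD", "eTRW")
JAW_MEASUREMENTS_REQUIRED <- c("ML", "ASD", "MSL", "MSD", "TRL", "CPD",
                               "RPL", "maL", "LCH")

JAW_TABLE_COLUMNS <- c("specimen_id", "taxon", "clade", "sublineage",
                       "guild", "time_bin", JAW_MEASUREMENTS, "source_note")

## the 11 morphospace characters, in fixed order, plus auxiliaries
JAW_CHARACTERS <- c("ASD.ML", "MSL.ML", "MSD.ML", "TRL.ML", "CPD.ML",
                    "RPL.ML", "TI", "maL.ML", "aMA", "pMA", "oMA")

#' Coarsen clade labels to family rank
#'
#' Maps Metriorhynchinae and Geosaurinae to their joint family
#' Metriorhynchidae; all other clade labels pass through unchanged.
#'
#' @param clade character vector of clade labels.
#' @return character vector of the same length.
#' @export
#' @examples
#' coarsen_clade(c("Geosaurinae", "Pliosauridae"))
coarsen_clade <- function(clade) {
  ifelse(clade %in% c("Metriorhynchinae", "Geosaurinae"),
         "Metriorhynchidae", clade)
}

#' Merge the two Pierce guilds
#'
#' @param guild character vector of guild labels.
#' @return character vector with "Pierce I" and "Pierce II" both mapped
#'   to "Pierce".
#' @export
collapse_pierce <- function(guild) {
  ifelse(guild %in% c("Pierce I", "Pierce II"), "Pierce", guild)
}
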