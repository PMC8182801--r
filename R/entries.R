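entry_columns <- c("refcode", "a", "b", "c", "alpha", "beta", "gamma",
                   "temperature_K", "r_factor", "pressure_flag", "has_coords",
                   "organic", "polymeric", "publication_id")

#' Read a structure-determination table
#'
#' Reads the flat CSV of crystal-structure determinations that the survey
#' operates on: one row per entry with a refcode, the six unit-cell
#' parameters, the analysis temperature (empty when the publication did not
#' record one), the crystallographic R-factor, a non-ambient-pressure flag,
#' quality flags and a publication identifier.
#'
#' @param path Path to a CSV file with columns
#'   `refcode, a, b, c, alpha, beta, gamma, temperature_K, r_factor,
#'   pressure_flag, has_coords, organic, polymeric, publication_id`
#'   (empty field = missing).
#' @return A data.frame of entries.
#' @export
read_entries_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(refcode = "character",
                                       publication_id = "character"))
  validate_entries(df)
}

#' Validate an entry table
#'
#' Checks the schema and row-level invariants of an entry table and normalises
#' column types. Problems are reported together, itemised by row.
#'
#' @param entries A data.frame of structure determinations.
#' @return The validated data.frame (invisibly classed as before).
#' @export
validate_entries <- function(entries) {
  missing_cols <- setdiff(entry_columns, names(entries))
  if (length(missing_cols) > 0) {
    stop("entry table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  entries <- entries[entry_columns]
  for (col in c("a", "b", "c", "alpha", "beta", "gamma", "temperature_K", "r_factor")) {
    entries[[col]] <- as.numeric(entries[[col]])
  }
  for (col in c("pressure_flag", "has_coords", "organic", "polymeric")) {
    entries[[col]] <- as.logical(entries[[col]])
  }
  problems <- character(0)
  bad_ref <- which(is.na(entries$refcode) | !nzchar(entries$refcode))
  if (length(bad_ref) > 0) {
    problems <- c(problems, paste0("empty refcode in rows ",
                                   paste(bad_ref, collapse = ", ")))
  }
  bad_T <- which(!is.na(entries$temperature_K) &
                   (entries$temperature_K <= 0 | entries$temperature_K >= 1000))
  if (length(bad_T) > 0) {
    problems <- c(problems, paste0("temperature outside (0, 1000) K in rows ",
                                   paste(bad_T, collapse = ", ")))
  }
  for (i in seq_len(nrow(entries))) {
    ok <- tryCatch({
      validate_unit_cell(as.numeric(entries[i, c("a", "b", "c", "alpha", "beta", "gamma")]))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) problems <- c(problems, paste0("invalid unit cell in row ", i))
  }
  if (length(problems) > 0) {
    stop("entry table validation failed:\n  ", paste(problems, collapse = "\n  "))
  }
  entries
}

#' Screen entries on the survey's inclusion constraints
#'
#' Keeps organic, non-polymeric, ambient-pressure entries with 3-D
#' coordinates; everything else is excluded up front, before any family
#' building. Row order is preserved.
#'
#' @param entries A validated entry table.
#' @return A list with `kept` (the surviving rows) and `rejected` (the removed
#'   rows with a `reason` column: one of `pressure`, `no_coords`,
#'   `not_organic`, `polymeric`; the first failed constraint is recorded).
#' @export
screen_entries <- function(entries) {
  reason <- rep(NA_character_, nrow(entries))
  reason[!entries$organic %in% TRUE] <- "not_organic"
  reason[entries$polymeric %in% TRUE] <- "polymeric"
  reason[!entries$has_coords %in% TRUE] <- "no_coords"
  reason[entries$pressure_flag %in% TRUE] <- "pressure"
  rejected <- entries[!is.na(reason), , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- reason[!is.na(reason)]
  else rejected$reason <- character(0)
  list(kept = entries[is.na(reason), , drop = FALSE], rejected = rejected)
}

#' Assign analysis temperatures
#'
#' Entries without a recorded temperature are taken to have been measured at
#' room temperature and assigned 293 K. Recorded temperatures pass through
#' unchanged; explicit values within the nominal room-temperature range are
#' deliberately not snapped to 293 K.
#'
#' @param entries An entry table (or a single numeric temperature).
#' @param room_temperature_K Value assigned to missing temperatures.
#' @return The table with `temperature_K` filled in (or the scalar).
#' @export
assign_temperature <- function(entries, room_temperature_K = 293) {
  if (!is.data.frame(entries)) {
    t <- as.numeric(entries)
    t[is.na(t)] <- room_temperature_K
    return(t)
  }
  entries$temperature_K[is.na(entries$temperature_K)] <- room_temperature_K
  entries
}

# 6-letter family root of a refcode ("ABCDEF01" -> "ABCDEF")
refcode_root <- function(refcode) substr(refcode, 1, 6)
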