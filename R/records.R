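# Interaction-record data model: one row per communicative act.

#' Column levels for interaction records
#'
#' Fixed vocabularies for the categorical fields of an interaction-record
#' table: species, research setting, sex, partner class and the seven
#' presumed social-goal categories.
#'
#' @format A named list of character vectors.
#' @export
record_levels <- list(
  species       = c("bornean", "sumatran"),
  setting       = c("wild", "captive"),
  sex           = c("female", "male"),
  partner_class = c("mother", "peer", "older"),
  social_goal   = c("co_locomote", "share_food_object", "groom",
                    "play_affiliate", "move_away", "sexual_contact",
                    "stop_action")
)

record_columns <- c("record_id", "individual_id", "species", "setting",
                    "group_id", "sex", "age_years", "partner_class",
                    "signal_type", "social_goal")

#' Validate an interaction-record table
#'
#' Checks a data frame of communicative-act records against the data model:
#' all required columns present, categorical fields restricted to their
#' fixed vocabularies ([record_levels]), non-negative numeric ages,
#' non-empty signal types, unique record ids, and species / setting /
#' group / sex consistent within each individual. Violations are reported
#' with the offending row number and field.
#'
#' Ages are expected to be constant per individual over the study period;
#' if several distinct ages occur for one individual they are replaced by
#' their mean with a warning.
#'
#' @param records data frame with the columns listed in the error messages.
#' @return The validated (possibly age-averaged) data frame, with
#'   character columns, invisibly classed as before.
#' @seealso [read_records()], [profile_individuals()]
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(record_columns, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in setdiff(record_columns, "age_years")) {
    records[[col]] <- as.character(records[[col]])
  }

  fail <- function(rows, field, msg) {
    stop(sprintf("row %s: field '%s' %s", rows[1L], field, msg))
  }

  if (anyDuplicated(records$record_id)) {
    dup <- which(duplicated(records$record_id))
    fail(dup, "record_id", "duplicated")
  }
  for (field in names(record_levels)) {
    bad <- which(!(records[[field]] %in% record_levels[[field]]))
    if (length(bad) > 0L) {
      fail(bad, field, sprintf("has unknown level '%s' (allowed: %s)",
                               records[[field]][bad[1L]],
                               paste(record_levels[[field]], collapse = ", ")))
    }
  }
  age <- suppressWarnings(as.numeric(records$age_years))
  bad <- which(is.na(age))
  if (length(bad) > 0L) fail(bad, "age_years", "is not a number")
  bad <- which(age < 0)
  if (length(bad) > 0L) fail(bad, "age_years", "is negative")
  records$age_years <- age
  bad <- which(is.na(records$signal_type) | records$signal_type == "")
  if (length(bad) > 0L) fail(bad, "signal_type", "is empty")

  # per-individual attribute consistency
  for (field in c("species", "setting", "group_id", "sex")) {
    tab <- unique(records[, c("individual_id", field)])
    dup <- tab$individual_id[duplicated(tab$individual_id)]
    if (length(dup) > 0L) {
      rows <- which(records$individual_id == dup[1L])
      fail(rows, field,
           sprintf("is inconsistent across records of individual '%s'", dup[1L]))
    }
  }
  ages <- tapply(records$age_years, records$individual_id,
                 function(a) length(unique(a)))
  multi <- names(ages)[ages > 1L]
  if (length(multi) > 0L) {
    warning("multiple ages for individual(s) ",
            paste(multi, collapse = ", "), "; using per-individual means")
    mean_age <- tapply(records$age_years, records$individual_id, mean)
    records$age_years <- as.vector(mean_age[records$individual_id])
  }
  records
}

#' Read and validate interaction records from CSV
#'
#' Reads a UTF-8, comma-separated file with a header row and validates it
#' with [validate_records()]. `col_map` adapts foreign column headers to
#' the package's schema (named character vector, `c(schema_name =
#' file_name)`), the adaptation point for externally deposited tables
#' whose headers differ from this package's spellings.
#'
#' @param path path to a CSV file.
#' @param col_map optional named character vector renaming file columns to
#'   schema columns.
#' @return A validated records data frame in file order.
#' @export
read_records <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = "character", encoding = "UTF-8")
  if (!is.null(col_map)) {
    for (schema_name in names(col_map)) {
      file_name <- col_map[[schema_name]]
      if (!file_name %in% names(records)) {
        stop("col_map refers to absent column '", file_name, "'")
      }
      names(records)[names(records) == file_name] <- schema_name
    }
  }
  validate_records(records)
}

#' Write interaction records to CSV
#'
#' Inverse of [read_records()]: writes the schema columns in canonical
#' order so that a written file reads back field-for-field identical.
#'
#' @param records validated records data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records[, record_columns], path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-individual profiles with observation effort by partner class
#'
#' Collapses a record table to one row per individual, carrying the fixed
#' attributes and the number of signal instances (observation effort)
#' contributed towards each partner class. `other`-scope effort is always
#' derived as peer + older, never stored.
#'
#' @param records validated records data frame.
#' @return data frame with one row per individual: `individual_id`,
#'   `species`, `setting`, `group_id`, `sex`, `age_years`,
#'   `effort_mother`, `effort_peer`, `effort_older`.
#' @export
profile_individuals <- function(records) {
  cols <- c("individual_id", "species", "setting", "group_id", "sex",
            "age_years")
  if (nrow(records) == 0L) {
    out <- data.frame(matrix(nrow = 0L, ncol = length(cols)))
    names(out) <- cols
    out$effort_mother <- integer(0)
    out$effort_peer <- integer(0)
    out$effort_older <- integer(0)
    return(out)
  }
  prof <- unique(records[, cols])
  prof <- prof[order(prof$individual_id), , drop = FALSE]
  rownames(prof) <- NULL
  counts <- table(factor(records$individual_id, levels = prof$individual_id),
                  factor(records$partner_class,
                         levels = record_levels$partner_class))
  prof$effort_mother <- as.integer(counts[, "mother"])
  prof$effort_peer <- as.integer(counts[, "peer"])
  prof$effort_older <- as.integer(counts[, "older"])
  prof
}

#' Observation effort of each individual within a partner scope
#'
#' @param profiles output of [profile_individuals()].
#' @param scope one of `"mother"`, `"other"`, `"peer"`, `"older"`;
#'   `"other"` is the union of peer and older.
#' @return Named integer vector of signal-instance counts.
#' @export
scope_effort <- function(profiles, scope) {
  scope <- match.arg(scope, c("mother", "other", "peer", "older"))
  eff <- switch(scope,
    mother = profiles$effort_mother,
    peer   = profiles$effort_peer,
    older  = profiles$effort_older,
    other  = profiles$effort_peer + profiles$effort_older
  )
  stats::setNames(as.integer(eff), profiles$individual_id)
}

# records falling inside a partner scope
scope_records <- function(records, scope) {
  scope <- match.arg(scope, c("mother", "other", "peer", "older"))
  keep <- switch(scope,
    mother = records$partner_class == "mother",
    peer   = records$partner_class == "peer",
    older  = records$partner_class == "older",
    other  = records$partner_class %in% c("peer", "older")
  )
  records[keep, , drop = FALSE]
}

#' Write per-individual profiles to JSON
#'
#' @param profiles output of [profile_individuals()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  jsonlite::write_json(profiles, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
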