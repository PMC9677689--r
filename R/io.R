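# CSV interchange. Plain RFC-4180 CSV with a header row, UTF-8, empty string
# for missing values, booleans as 0/1. Rows are written in a canonical sort
# order so repeated writes of the same cohort are byte-identical.

CARRIER_COLS <- c("carrier_id", "gene", "gender", "region", "carrier_status")
FOLLOWUP_COLS <- c("carrier_id", "age_at_inclusion",
                   "age_at_last_observation", "dead", "age_at_death")
EVENT_COLS <- c("carrier_id", "organ", "age_at_diagnosis")

read_csv_checked <- function(path, cols, int_cols = character(),
                             bool_cols = character()) {
  if (!file.exists(path)) {
    lc_error(sprintf("file not found: %s", path), "lynchcohort_io_error")
  }
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE, na.strings = NULL)
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    lc_error(sprintf("%s: missing column(s): %s", basename(path),
                     paste(miss, collapse = ", ")),
             "lynchcohort_missing_column", columns = miss)
  }
  df <- df[cols]
  for (cc in int_cols) {
    raw <- df[[cc]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!(raw == "") & (is.na(val) | val != trunc(val)))
    if (length(bad)) {
      lc_error(sprintf("%s: column '%s', row %d: '%s' is not a whole number",
                       basename(path), cc, bad[1L], raw[bad[1L]]),
               "lynchcohort_type_error", column = cc, row = bad[1L])
    }
    val[raw == ""] <- NA
    df[[cc]] <- as.integer(val)
  }
  for (cc in bool_cols) {
    raw <- df[[cc]]
    ok <- raw %in% c("0", "1", "TRUE", "FALSE", "true", "false")
    if (any(!ok)) {
      i <- which(!ok)[1L]
      lc_error(sprintf("%s: column '%s', row %d: '%s' is not a 0/1 boolean",
                       basename(path), cc, i, raw[i]),
               "lynchcohort_type_error", column = cc, row = i)
    }
    df[[cc]] <- raw %in% c("1", "TRUE", "true")
  }
  df
}

#' Read a cohort from its three CSV tables
#'
#' Reads the carriers, follow-up and events tables, type-checks every cell,
#' and validates the assembled cohort. Import never silently drops rows:
#' every row is either accepted or named in an error.
#'
#' Expected headers:
#' \preformatted{
#' carriers.csv:  carrier_id,gene,gender,region,carrier_status
#' followup.csv:  carrier_id,age_at_inclusion,age_at_last_observation,dead,age_at_death
#' events.csv:    carrier_id,organ,age_at_diagnosis
#' }
#' Ages are whole years; `dead` is 0/1; missing `age_at_death` is the empty
#' string.
#'
#' @param carriers_path,followup_path,events_path paths to the CSV files.
#' @param gene_levels,organ_levels vocabularies passed to [lynch_cohort()].
#' @param validate fail on a non-empty validation report (default `TRUE`).
#' @return A validated [lynch_cohort] object.
#' @seealso [write_cohort()] for the inverse; `read(write(cohort))` is the
#'   identity for every valid cohort.
#' @export
read_cohort <- function(carriers_path, followup_path, events_path,
                        gene_levels = mmr_genes,
                        organ_levels = organ_vocabulary,
                        validate = TRUE) {
  carriers <- read_csv_checked(carriers_path, CARRIER_COLS)
  followup <- read_csv_checked(
    followup_path, FOLLOWUP_COLS,
    int_cols = c("age_at_inclusion", "age_at_last_observation",
                 "age_at_death"),
    bool_cols = "dead")
  events <- read_csv_checked(events_path, EVENT_COLS,
                             int_cols = "age_at_diagnosis")
  lynch_cohort(carriers, followup, events, gene_levels = gene_levels,
               organ_levels = organ_levels, validate = validate)
}

fmt_csv_cell <- function(x) {
  if (is.logical(x)) return(as.character(as.integer(x)))
  out <- as.character(x)
  out[is.na(x)] <- ""
  out
}

write_csv_plain <- function(df, path) {
  cells <- vapply(df, fmt_csv_cell, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(paste(names(df), collapse = ","),
             if (nrow(df)) apply(cells, 1L, paste, collapse = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a cohort to three CSV files
#'
#' Writes `carriers.csv`, `followup.csv` and `events.csv` under `dir_path`
#' in the layout [read_cohort()] expects. Rows are sorted by carrier id
#' (events additionally by organ and age) so output is byte-stable across
#' repeated calls.
#'
#' @param cohort a valid [lynch_cohort].
#' @param dir_path output directory, created if needed.
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir_path) {
  stopifnot(inherits(cohort, "lynch_cohort"))
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  car <- cohort$carriers[order(cohort$carriers$carrier_id), CARRIER_COLS,
                         drop = FALSE]
  fu <- cohort$followup[order(cohort$followup$carrier_id), FOLLOWUP_COLS,
                        drop = FALSE]
  ev <- cohort$events[order(cohort$events$carrier_id, cohort$events$organ,
                            cohort$events$age_at_diagnosis), EVENT_COLS,
                      drop = FALSE]
  paths <- file.path(dir_path, c("carriers.csv", "followup.csv", "events.csv"))
  write_csv_plain(car, paths[1L])
  write_csv_plain(fu, paths[2L])
  write_csv_plain(ev, paths[3L])
  invisible(paths)
}

#' Export a result table as CSV
#'
#' Writes any of the engine's result tables (age-cohort incidence tables,
#' cumulative incidence curves, K-M rows, count summaries) as plain CSV for
#' further processing in other applications. Column order is the object's
#' documented order; floating-point cells are rendered with 6 significant
#' digits; missing values are empty.
#'
#' @param result_table a data.frame.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(result_table, path) {
  df <- as.data.frame(result_table)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- trimws(formatC(df[[j]], digits = 6, format = "g"))
      v[is.na(df[[j]])] <- ""
      df[[j]] <- v
    }
  }
  write_csv_plain(df, path)
}
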