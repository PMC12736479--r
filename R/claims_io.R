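# Reading, validating and writing dispensing-claims and death-registry
# tables. The canonical dialect is comma-separated UTF-8 text with a header
# row and ISO 8601 dates; a dialect object allows locale variations.

DISPENSING_COLUMNS <- c("patient_id", "birth_date", "sex", "dispense_date",
                        "atc_code", "medication_name", "n_packages")

#' Claims-file dialect
#'
#' Describes the delimited-text dialect of a claims export: field delimiter,
#' date format, and whether ingest is strict (any malformed row is an error)
#' or lenient (malformed rows are skipped and reported).
#'
#' @param delimiter Single field-separator character. Default `","`.
#' @param date_format Date format string understood by [base::as.Date()].
#'   Default ISO 8601, `"%Y-%m-%d"`.
#' @param strict Logical; `TRUE` aborts on the first malformed row, `FALSE`
#'   skips malformed rows and records them in the `errors` attribute of the
#'   result.
#' @return An object of class `"claims_dialect"`.
#' @examples
#' claims_dialect()                      # canonical: CSV, ISO dates, strict
#' claims_dialect(";", "%d/%m/%Y", strict = FALSE)
#' @export
claims_dialect <- function(delimiter = ",", date_format = "%Y-%m-%d",
                           strict = TRUE) {
  stopifnot(is.character(delimiter), nchar(delimiter) == 1L,
            is.character(date_format), is.logical(strict))
  structure(list(delimiter = delimiter, date_format = date_format,
                 strict = strict),
            class = "claims_dialect")
}

#' Read a dispensing-claims table
#'
#' Reads one-row-per-dispensation claims: anonymized patient id, birth date,
#' sex, dispensation date, ATC level-5 code, medication name and number of
#' packages, with an optional `unit_dose_mg` column. ATC codes are
#' uppercased on ingest and validated against the level-5 pattern (a letter,
#' two digits, two letters, two digits); sexes outside M/F are mapped to
#' `"U"` and retained.
#'
#' Malformed rows (unparseable date, invalid ATC code, non-positive package
#' count, dispensation before birth) are fatal in strict mode; in lenient
#' mode they are dropped and collected, with their row numbers, in the
#' `errors` attribute of the returned data frame. A missing mandatory column
#' is always fatal.
#'
#' @param source Path to a delimited text file with a header row.
#' @param dialect A [claims_dialect()].
#' @return A data frame with columns `patient_id`, `birth_date` (`Date`),
#'   `sex` (`"M"/"F"/"U"`), `dispense_date` (`Date`), `atc_code`,
#'   `medication_name`, `n_packages` (integer) and `unit_dose_mg` (numeric,
#'   `NA` when absent), in file order. Attribute `errors` holds a data frame
#'   of rejected rows (`row`, `message`).
#' @seealso [write_records()], [read_deaths()]
#' @export
read_dispensing <- function(source, dialect = claims_dialect()) {
  stopifnot(inherits(dialect, "claims_dialect"))
  raw <- utils::read.table(source, header = TRUE, sep = dialect$delimiter,
                           colClasses = "character", quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           encoding = "UTF-8", check.names = TRUE)
  missing_cols <- setdiff(DISPENSING_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("dispensing file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  out <- data.frame(
    patient_id = raw$patient_id,
    birth_date = parse_iso_date(raw$birth_date, dialect$date_format),
    sex = toupper(trimws(raw$sex)),
    dispense_date = parse_iso_date(raw$dispense_date, dialect$date_format),
    atc_code = toupper(trimws(raw$atc_code)),
    medication_name = raw$medication_name,
    n_packages = suppressWarnings(as.integer(raw$n_packages)),
    stringsAsFactors = FALSE
  )
  out$unit_dose_mg <- if ("unit_dose_mg" %in% names(raw)) {
    suppressWarnings(as.numeric(raw$unit_dose_mg))
  } else {
    rep(NA_real_, n)
  }
  out$sex[!(out$sex %in% c("M", "F"))] <- "U"

  problems <- character(n)
  bad_date <- is.na(out$birth_date) | is.na(out$dispense_date)
  problems[bad_date] <- "unparseable date"
  bad_atc <- !bad_date & !is_valid_atc_code(out$atc_code)
  problems[bad_atc] <- "invalid ATC level-5 code"
  bad_pkg <- problems == "" & (is.na(out$n_packages) | out$n_packages < 1L)
  problems[bad_pkg] <- "n_packages must be a positive integer"
  bad_ord <- problems == "" & out$dispense_date < out$birth_date
  problems[bad_ord] <- "dispense_date precedes birth_date"

  bad <- which(problems != "")
  errors <- data.frame(row = bad, message = problems[bad],
                       stringsAsFactors = FALSE)
  if (length(bad) > 0L) {
    if (dialect$strict) {
      stop("malformed dispensing row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "),
           if (length(bad) > 5L) " ..." else "", ": ",
           paste(unique(problems[bad]), collapse = "; "))
    }
    out <- out[-bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "errors") <- errors
  out
}

#' Read a death-registry table
#'
#' Reads `patient_id,death_date` rows. Duplicate patient ids keep the
#' earliest death date, with a warning.
#'
#' @inheritParams read_dispensing
#' @return A data frame with columns `patient_id` and `death_date` (`Date`),
#'   one row per patient.
#' @export
read_deaths <- function(source, dialect = claims_dialect()) {
  stopifnot(inherits(dialect, "claims_dialect"))
  raw <- utils::read.table(source, header = TRUE, sep = dialect$delimiter,
                           colClasses = "character", quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           encoding = "UTF-8")
  missing_cols <- setdiff(c("patient_id", "death_date"), names(raw))
  if (length(missing_cols) > 0L) {
    stop("death-registry file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    patient_id = raw$patient_id,
    death_date = parse_iso_date(raw$death_date, dialect$date_format),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(out$death_date))
  if (length(bad) > 0L) {
    if (dialect$strict) {
      stop("unparseable death_date in row(s) ", paste(bad, collapse = ", "))
    }
    out <- out[-bad, , drop = FALSE]
  }
  if (anyDuplicated(out$patient_id)) {
    warning("duplicate patient_id in death registry; keeping earliest date")
    out <- out[order(out$patient_id, out$death_date), , drop = FALSE]
    out <- out[!duplicated(out$patient_id), , drop = FALSE]
    out <- out[order(match(out$patient_id, raw$patient_id)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write dispensing records
#'
#' Writes records in the claims dialect so that reading the file back
#' reproduces the input exactly (round trip). Fields containing the
#' delimiter or quotes are quoted.
#'
#' @param records Data frame as returned by [read_dispensing()].
#' @param sink Output file path.
#' @param dialect A [claims_dialect()].
#' @return Invisibly, the number of data rows written (excluding header).
#' @export
write_records <- function(records, sink, dialect = claims_dialect()) {
  stopifnot(inherits(dialect, "claims_dialect"))
  out <- records[, intersect(c(DISPENSING_COLUMNS, "unit_dose_mg"),
                             names(records)), drop = FALSE]
  for (col in c("birth_date", "dispense_date")) {
    out[[col]] <- format(out[[col]], dialect$date_format)
  }
  utils::write.table(out, sink, sep = dialect$delimiter, row.names = FALSE,
                     col.names = TRUE, qmethod = "double", quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(nrow(out))
}
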