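#' Parse heterogeneous CGM timestamp strings
#'
#' Donated entries files mix several timestamp dialects: ISO 8601 with `T`
#' and `Z` markers (`"2018-08-04T23:58:50Z"`), plain
#' `"YYYY-MM-DD HH:MM:SS"`, strings prefixed with a day-of-week abbreviation
#' (`"Mon 2018-08-06 07:00:00"`), and strings suffixed with a timezone
#' abbreviation (`"2018-08-04 23:58:50 GMT"`). All are normalised to a
#' timezone-naive wall-clock date-time: hour-of-day analyses are behavioural
#' and local, and per-row zone ground truth is not recoverable, so zone
#' markers are recognised (against a fixed abbreviation table) and dropped.
#' Unrecognised strings return `NA` so the caller can count and drop them.
#'
#' @param raw Character vector of raw timestamp strings.
#' @return POSIXct vector (UTC-encoded wall-clock time); `NA` where
#'   unparseable.
#' @examples
#' parse_timestamp(c("2018-08-04T23:58:50Z",
#'                   "Mon 2018-08-06 07:00:00",
#'                   "2018-08-04 23:58:50 PDT",
#'                   "not-a-date"))
#' @export
parse_timestamp <- function(raw) {
  x <- trimws(as.character(raw))
  x[!nzchar(x)] <- NA_character_

  # day-of-week prefix
  dow <- "^(Mon|Tue|Wed|Thu|Fri|Sat|Sun),?\\s+"
  x <- sub(dow, "", x)
  # ISO T / trailing Z
  x <- sub("^(\\d{4}-\\d{2}-\\d{2})T", "\\1 ", x)
  x <- sub("Z$", "", x)
  # trailing timezone abbreviation: known ones are stripped, unknown ones
  # leave the string unparseable
  known_tz <- c("GMT", "UTC", "PDT", "PST", "EDT", "EST", "CDT", "CST",
                "MDT", "MST", "CES", "CEST", "CET", "BST")
  has_tz <- grepl(" [A-Z]{2,4}$", x)
  if (any(has_tz, na.rm = TRUE)) {
    idx <- which(has_tz)
    abb <- sub("^.* ", "", x[idx])
    ok <- abb %in% known_tz
    x[idx[ok]] <- sub(" [A-Z]{2,4}$", "", x[idx[ok]])
  }
  # optional fractional seconds
  x <- sub("(\\d{2}:\\d{2}:\\d{2})\\.\\d+$", "\\1", x)

  out <- lubridate::fast_strptime(x, "%Y-%m-%d %H:%M:%S", tz = "UTC",
                                  lt = FALSE)
  # date-only rows are not CGM readings at second resolution; leave NA
  out
}

empty_cleaning_report <- function() {
  tibble::tibble(rows_in = 0L, null_removed = 0L, nonfinite_removed = 0L,
                 unparseable_timestamp_removed = 0L, below_39_removed = 0L,
                 above_1000_removed = 0L, clamped_to_400 = 0L,
                 duplicates_removed = 0L, rows_out = 0L)
}

#' Apply device-error value-cleaning rules to raw glucose readings
#'
#' Implements the error-term rules for sensor glucose values in mg/dL:
#' rows whose value is the text `"null"` are dropped; non-finite or
#' non-numeric values (`"inf"`, `NaN`) are dropped; values below 39 are
#' device error codes and dropped; values above 1000 are dropped; values
#' greater than 400 and at most 1000 are replaced with 400 (the sensor
#' ceiling). No interpolation is performed. Every action is counted in the
#' returned audit report.
#'
#' @param rows A data frame with columns `timestamp` (POSIXct, may contain
#'   `NA` for unparseable rows) and `value` (character or numeric raw sgv).
#' @return A list with `rows` (tibble `timestamp`, `glucose` of retained
#'   readings) and `report` (one-row tibble of counters; `rows_out` and
#'   `duplicates_removed` are completed by [merge_and_deduplicate()] /
#'   [load_individual()]).
#' @examples
#' rows <- tibble::tibble(
#'   timestamp = as.POSIXct("2020-01-01", tz = "UTC") + 1:6 * 300,
#'   value = c("38", "39", "100", "450", "1001", "null"))
#' clean_values(rows)
#' @export
clean_values <- function(rows) {
  stopifnot(all(c("timestamp", "value") %in% names(rows)))
  report <- empty_cleaning_report()
  report$rows_in <- nrow(rows)
  if (nrow(rows) == 0) return(list(rows = empty_series(), report = report))

  raw <- trimws(as.character(rows$value))
  is_null <- !is.na(raw) & tolower(raw) == "null"
  report$null_removed <- sum(is_null)

  num <- suppressWarnings(as.numeric(raw))
  num[grepl("^[+-]?inf(inity)?$", tolower(raw))] <- Inf
  is_nonfinite <- !is_null & (!is.finite(num) | is.na(raw))
  report$nonfinite_removed <- sum(is_nonfinite)

  is_unparseable <- is.na(rows$timestamp) & !is_null & !is_nonfinite
  report$unparseable_timestamp_removed <- sum(is_unparseable)

  candidate <- !is_null & !is_nonfinite & !is_unparseable
  val <- num
  is_low <- candidate & val < 39
  is_high <- candidate & val > 1000
  report$below_39_removed <- sum(is_low)
  report$above_1000_removed <- sum(is_high)

  keep <- candidate & !is_low & !is_high
  clamp <- keep & val > 400            # (400, 1000] -> 400
  report$clamped_to_400 <- sum(clamp)
  val[clamp] <- 400

  out <- tibble::tibble(timestamp = rows$timestamp[keep],
                        glucose = val[keep])
  report$rows_out <- nrow(out)
  list(rows = out, report = report)
}

empty_series <- function() {
  tibble::tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                 glucose = numeric())
}

#' Merge per-file reading lists and remove duplicate timestamps
#'
#' Concatenates the (already value-cleaned) rows of all files belonging to
#' one individual, sorts them in increasing timestamp order with a stable
#' sort (preserving input-file order among ties), and keeps only the first
#' row for each duplicated timestamp. Duplicates are defined by identical
#' timestamp at second resolution; values are not compared. The result has
#' strictly increasing timestamps and the operation is idempotent.
#'
#' @param file_series A list of tibbles with columns `timestamp`,
#'   `glucose`, or a single such tibble.
#' @return A list with `rows` (merged tibble) and `duplicates_removed`
#'   (count).
#' @examples
#' t0 <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
#' a <- tibble::tibble(timestamp = c(t0, t0), glucose = c(100, 120))
#' merge_and_deduplicate(list(a))
#' @export
merge_and_deduplicate <- function(file_series) {
  if (is.data.frame(file_series)) file_series <- list(file_series)
  rows <- dplyr::bind_rows(file_series)
  if (nrow(rows) == 0) return(list(rows = empty_series(), duplicates_removed = 0L))
  ord <- order(rows$timestamp)          # base order() is stable
  rows <- rows[ord, ]
  dup <- duplicated(rows$timestamp)
  list(rows = tibble::as_tibble(rows[!dup, ]),
       duplicates_removed = sum(dup))
}

#' Load and clean one individual's entries files
#'
#' Full ingest pipeline for one individual: read every entries file in the
#' directory (CSV with columns `dateString` and `sgv`, extra columns
#' ignored; a JSON array variant with the same keys is also accepted), parse
#' timestamps, apply the value-cleaning rules, merge files, and
#' de-duplicate. The audit report aggregates every counter across files.
#'
#' @param directory Directory holding one or more entries files
#'   (`*.csv` / `*.json`) for a single individual.
#' @param individual_id Identifier to attach; defaults to the directory
#'   name.
#' @return A list with `series` (tibble `timestamp`, `glucose`, attribute
#'   `individual_id`) and `report` (one-row tibble, including
#'   `individual_id`). An input whose rows are all dropped yields an empty
#'   series with a complete report.
#' @export
load_individual <- function(directory, individual_id = basename(directory)) {
  if (!dir.exists(directory)) stop("no such directory: ", directory)
  files <- sort(list.files(directory, pattern = "\\.(csv|json)$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no entries files in ", directory)

  per_file <- vector("list", length(files))
  reports <- vector("list", length(files))
  for (i in seq_along(files)) {
    raw <- read_entries_file(files[i])
    raw$timestamp <- parse_timestamp(raw$dateString)
    cleaned <- clean_values(tibble::tibble(timestamp = raw$timestamp,
                                           value = raw$sgv))
    per_file[[i]] <- cleaned$rows
    reports[[i]] <- cleaned$report
  }
  merged <- merge_and_deduplicate(per_file)

  report <- dplyr::summarise(dplyr::bind_rows(reports),
                             dplyr::across(dplyr::everything(), sum))
  report$duplicates_removed <- merged$duplicates_removed
  report$rows_out <- nrow(merged$rows)
  report <- tibble::as_tibble(cbind(individual_id = individual_id, report))

  series <- merged$rows
  attr(series, "individual_id") <- individual_id
  list(series = series, report = report)
}

read_entries_file <- function(path) {
  if (grepl("\\.json$", path)) {
    df <- jsonlite::fromJSON(path)
    df <- tibble::as_tibble(df)
  } else {
    # force character: fread would otherwise auto-parse ISO timestamps and
    # midnight rows would lose their time component on re-stringification
    df <- data.table::fread(path, showProgress = FALSE,
                            colClasses = list(character = c("dateString",
                                                            "sgv")))
    df <- tibble::as_tibble(df)
  }
  if (!all(c("dateString", "sgv") %in% names(df))) {
    stop("entries file lacks dateString/sgv columns: ", path)
  }
  df$sgv <- as.character(df$sgv)
  df$dateString <- as.character(df$dateString)
  df[, c("dateString", "sgv")]
}

#' Load and clean every individual in a cohort directory
#'
#' Applies [load_individual()] to each sub-directory of `root` and returns
#' the cleaned series plus a combined audit report (one row per
#' individual).
#'
#' @param root Directory containing one sub-directory of entries files per
#'   individual.
#' @return A list with `series` (named list of cleaned tibbles) and
#'   `reports` (tibble).
#' @export
load_cohort <- function(root) {
  if (!dir.exists(root)) stop("no such directory: ", root)
  dirs <- list.dirs(root, recursive = FALSE)
  if (length(dirs) == 0) stop("no individual directories under ", root)
  out <- lapply(dirs, load_individual)
  list(series = setNames(lapply(out, `[[`, "series"), basename(dirs)),
       reports = dplyr::bind_rows(lapply(out, `[[`, "report")))
}

#' Write a cleaned series to canonical CSV
#'
#' Canonical output format: `timestamp` as `"YYYY-MM-DD HH:MM:SS"` and
#' `glucose_mgdl` as integer.
#'
#' @param series Cleaned series tibble (`timestamp`, `glucose`).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_clean_series <- function(series, path) {
  out <- data.table::data.table(
    timestamp = format(series$timestamp, "%Y-%m-%d %H:%M:%S"),
    glucose_mgdl = as.integer(round(series$glucose)))
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read a canonical cleaned-series CSV
#'
#' @param path File written by [write_clean_series()].
#' @return Tibble with `timestamp` (POSIXct) and `glucose`.
#' @export
read_clean_series <- function(path) {
  df <- data.table::fread(path, showProgress = FALSE,
                          colClasses = list(character = "timestamp"))
  ts <- df$timestamp
  ts[nchar(ts) == 10] <- paste(ts[nchar(ts) == 10], "00:00:00")
  tibble::tibble(
    timestamp = lubridate::fast_strptime(ts, "%Y-%m-%d %H:%M:%S",
                                         tz = "UTC", lt = FALSE),
    glucose = as.numeric(df$glucose_mgdl))
}
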