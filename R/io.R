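## CSV interfaces: hourly series in (`timestamp,api`), event catalogs out/in
## (`start,duration_hours,severity,censored_end`).

#' Read an hourly API series from CSV
#'
#' Expects a header `timestamp,api`; ISO-8601 timestamps; missing values as
#' empty fields or `NA`.
#'
#' @param path CSV file path.
#' @param quiet Suppress the gap-report message.
#' @return An [hourly_series()].
#' @export
read_api_series <- function(path, quiet = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  need <- c("timestamp", "api")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns `timestamp` and `api`", call. = FALSE)
  }
  hourly_series(df$timestamp, df$api, quiet = quiet)
}

#' Write an hourly API series to CSV
#'
#' @param series An [hourly_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_api_series <- function(series, path) {
  df <- data.frame(timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%S"),
                   api = series$api)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write an event catalog to CSV
#'
#' Columns `start,duration_hours,severity,censored_end`.
#'
#' @param catalog An [extract_events()] catalog.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_catalog <- function(catalog, path) {
  df <- data.frame(start = format(catalog$start, "%Y-%m-%dT%H:%M:%S"),
                   duration_hours = catalog$duration_hours,
                   severity = catalog$severity,
                   censored_end = catalog$censored_end)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an event catalog from CSV
#'
#' @param path CSV with columns `start,duration_hours,severity,censored_end`
#'   (as written by [write_event_catalog()]).
#' @param threshold Threshold recorded in the catalog attributes.
#' @return An `"event_catalog"` data frame.
#' @export
read_event_catalog <- function(path, threshold = 100) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start", "duration_hours", "severity")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns `start`, `duration_hours`, `severity`",
         call. = FALSE)
  }
  start <- as.POSIXct(sub("T", " ", df$start, fixed = TRUE), tz = "UTC")
  if (is.null(df$censored_end)) df$censored_end <- FALSE
  span <- if (nrow(df) >= 2L) {
    as.integer(round(diff(as.numeric(range(start))) / 3600)) +
      max(df$duration_hours)
  } else {
    max(df$duration_hours, 0L)
  }
  structure(data.frame(start = start,
                       duration_hours = as.integer(df$duration_hours),
                       severity = as.numeric(df$severity),
                       censored_end = as.logical(df$censored_end)),
            class = c("event_catalog", "data.frame"),
            threshold = threshold, series_span_hours = span,
            n_events = nrow(df))
}
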