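## Event extraction: from an hourly air-quality-index series to a catalog of
## unhealthy-pollution events with duration (consecutive unhealthy hours)
## and severity (cumulative index over the event).

#' Hourly air-quality-index series
#'
#' Validates and wraps an hourly API series. Timestamps must be strictly
#' increasing; nominal spacing is one hour. Gaps (missing rows) are detected
#' and reported via the `n_gaps` attribute and a message; values must be
#' nonnegative where not missing (`NA` is the missing marker).
#'
#' @param timestamps `POSIXct` vector (or anything coercible via
#'   [as.POSIXct()] with `tz = "UTC"`).
#' @param values Numeric API values, `NA` allowed.
#' @param quiet Suppress the gap-report message.
#' @return A data frame of class `"hourly_series"` with columns `timestamp`
#'   and `api`, and attribute `n_gaps` (count of missing hourly slots).
#' @examples
#' hourly_series(as.POSIXct("2020-01-01", tz = "UTC") + 3600 * (0:4),
#'               c(50, 101, 120, 99, 80))
#' @export
hourly_series <- function(timestamps, values, quiet = FALSE) {
  if (length(timestamps) == 0L) stop("empty series", call. = FALSE)
  if (!inherits(timestamps, "POSIXct")) {
    if (is.character(timestamps)) {
      timestamps <- sub("T", " ", timestamps, fixed = TRUE)  # ISO-8601
    }
    timestamps <- as.POSIXct(timestamps, tz = "UTC")
  }
  if (anyNA(timestamps)) stop("unparseable timestamps", call. = FALSE)
  values <- as.numeric(values)
  if (length(values) != length(timestamps)) {
    stop("timestamps and values must have equal length", call. = FALSE)
  }
  dt <- diff(as.numeric(timestamps)) / 3600
  if (any(dt <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("API values must be nonnegative", call. = FALSE)
  }
  n_gaps <- sum(round(dt) - 1)
  if (n_gaps > 0 && !quiet) {
    message(sprintf("hourly_series: %d missing hourly slot(s) detected",
                    n_gaps))
  }
  structure(data.frame(timestamp = timestamps, api = values),
            class = c("hourly_series", "data.frame"),
            n_gaps = n_gaps)
}

#' @export
print.hourly_series <- function(x, ...) {
  cat(sprintf("<hourly_series> %d hours, %s .. %s, %d missing value(s), %d gap(s)\n",
              nrow(x), format(x$timestamp[1]), format(x$timestamp[nrow(x)]),
              sum(is.na(x$api)), attr(x, "n_gaps")))
  invisible(x)
}

#' Extract unhealthy air-pollution events
#'
#' Scans the series for maximal runs of consecutive hours with API value
#' strictly above `threshold` (an hour at exactly the threshold terminates a
#' run). Each run becomes one event with duration \eqn{D_i} = run length in
#' hours and severity \eqn{S_i} = sum of the API values over the run. A run
#' still open at the last observation is emitted with `censored_end = TRUE`
#' (set `include_censored = FALSE` to drop it).
#'
#' Missing values are never ignored silently. Under
#' `missing_policy = "break"` (default) a missing hour terminates any open
#' run, exactly like a sub-threshold hour. Under `"bridge"`, up to
#' `bridge_k` consecutive missing hours flanked by exceeding hours are
#' skipped without breaking the run; bridged hours contribute to neither
#' duration nor severity. A gap in the timestamp grid always terminates an
#' open run.
#'
#' @param series An [hourly_series()] (or data frame with columns
#'   `timestamp`, `api`).
#' @param threshold Exceedance threshold; API above this is "unhealthy"
#'   (default 100).
#' @param missing_policy `"break"` or `"bridge"`.
#' @param bridge_k Maximum number of consecutive missing hours bridged when
#'   `missing_policy = "bridge"`.
#' @param include_censored Keep the final event when its run touches the end
#'   of the record.
#' @return A data frame of class `"event_catalog"` with columns `start`
#'   (POSIXct), `duration_hours`, `severity`, `censored_end`, and attributes
#'   `threshold`, `series_span_hours`, `n_events`.
#' @examples
#' ts <- as.POSIXct("2019-06-01", tz = "UTC") + 3600 * (0:6)
#' extract_events(hourly_series(ts, c(99, 105, 110, 99, 101, 102, 100)))
#' @export
extract_events <- function(series, threshold = 100,
                           missing_policy = c("break", "bridge"),
                           bridge_k = 3L, include_censored = TRUE) {
  if (!inherits(series, "hourly_series")) {
    series <- hourly_series(series$timestamp, series$api, quiet = TRUE)
  }
  missing_policy <- match.arg(missing_policy)
  stopifnot(threshold > 0)
  n <- nrow(series)
  val <- series$api
  ts <- series$timestamp

  exceed <- !is.na(val) & val > threshold
  ## hour is part of a run: exceeding, or a bridgeable missing stretch
  in_run <- exceed
  if (missing_policy == "bridge" && anyNA(val)) {
    r <- rle(is.na(val))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$lengths)) {
      if (!r$values[j] || r$lengths[j] > bridge_k) next
      a <- starts[j] - 1L; b <- ends[j] + 1L
      if (a >= 1L && b <= n && exceed[a] && exceed[b]) {
        in_run[starts[j]:ends[j]] <- TRUE
      }
    }
  }
  ## a timestamp gap breaks a run: split the record into contiguous blocks
  gap_after <- c(round(diff(as.numeric(ts)) / 3600) > 1, FALSE)
  block <- cumsum(c(0L, utils::head(gap_after, -1L)))

  r <- rle(paste0(in_run, ".", block))
  run_is <- grepl("^TRUE", r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L

  ev <- lapply(which(run_is), function(j) {
    idx <- starts[j]:ends[j]
    hit <- idx[exceed[idx]]
    data.frame(start = ts[hit[1L]],
               duration_hours = length(hit),
               severity = sum(val[hit]),
               censored_end = ends[j] == n)
  })
  ev <- if (length(ev)) do.call(rbind, ev) else
    data.frame(start = ts[0], duration_hours = integer(), severity = numeric(),
               censored_end = logical())
  if (!include_censored && nrow(ev)) ev <- ev[!ev$censored_end, , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev,
            class = c("event_catalog", "data.frame"),
            threshold = threshold,
            series_span_hours = as.integer(
              round(diff(as.numeric(range(ts))) / 3600)) + 1L,
            n_events = nrow(ev))
}

#' @export
print.event_catalog <- function(x, ...) {
  cat(sprintf("<event_catalog> %d event(s), threshold %g, span %d h\n",
              nrow(x), attr(x, "threshold"), attr(x, "series_span_hours")))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Mean inter-arrival time between events
#'
#' The expected inter-arrival time \eqn{E(L)} of pollution events, estimated
#' as the mean start-to-start gap between consecutive events, in days. This
#' is the time scale of all return-period computations.
#'
#' @param catalog An [extract_events()] catalog (or any data frame with a
#'   `start` column of event start times).
#' @return Mean inter-arrival time in days.
#' @examples
#' ts <- as.POSIXct("2019-01-01", tz = "UTC") + 3600 * (0:100)
#' v <- rep(50, 101); v[c(1, 49, 97)] <- 150
#' mean_interarrival_days(extract_events(hourly_series(ts, v)))
#' @export
mean_interarrival_days <- function(catalog) {
  if (nrow(catalog) < 2L) {
    stop("E(L) undefined: need at least 2 events to estimate inter-arrival time",
         call. = FALSE)
  }
  gaps_h <- diff(as.numeric(catalog$start)) / 3600
  mean(gaps_h) / 24
}

#' Moment-based descriptive statistics
#'
#' Mean, median, min, max, standard deviation, skewness and kurtosis of a
#' numeric vector. Skewness is the adjusted Fisher--Pearson sample skewness
#' (`e1071::skewness`, type 2); `kurtosis` is raw (non-excess, so a normal
#' sample gives about 3) and the excess version is reported alongside. A
#' constant vector reports skewness and excess kurtosis of 0 by convention.
#'
#' @param x Numeric vector, length at least 1; at least 3 values for
#'   skewness/kurtosis.
#' @return A one-row data frame with columns `n`, `mean`, `median`, `min`,
#'   `max`, `sd`, `skewness`, `kurtosis`, `excess_kurtosis`.
#' @examples
#' summary_stats(c(1, 2, 3, 10))
#' @export
summary_stats <- function(x) {
  if (length(x) == 0L || all(is.na(x))) stop("empty input", call. = FALSE)
  x <- x[!is.na(x)]
  constant <- length(unique(x)) == 1L
  skw <- if (constant || length(x) < 3L) 0 else e1071::skewness(x, type = 2)
  exk <- if (constant || length(x) < 4L) 0 else e1071::kurtosis(x, type = 2)
  data.frame(n = length(x), mean = mean(x), median = stats::median(x),
             min = min(x), max = max(x),
             sd = if (length(x) >= 2L) stats::sd(x) else NA_real_,
             skewness = skw, kurtosis = exk + 3, excess_kurtosis = exk)
}

#' Descriptive statistics of an event catalog
#'
#' [summary_stats()] applied to the duration and severity columns of a
#' catalog.
#'
#' @param catalog An [extract_events()] catalog.
#' @return A two-row data frame (rows `duration`, `severity`).
#' @export
catalog_stats <- function(catalog) {
  if (nrow(catalog) == 0L) stop("empty catalog", call. = FALSE)
  out <- rbind(summary_stats(catalog$duration_hours),
               summary_stats(catalog$severity))
  cbind(variable = c("duration", "severity"), out)
}

#' Proportion of unhealthy hours
#'
#' Fraction of non-missing hours with API value strictly above the
#' threshold.
#'
#' @inheritParams extract_events
#' @return A proportion in \eqn{[0, 1]}.
#' @examples
#' ts <- as.POSIXct("2019-01-01", tz = "UTC") + 3600 * (0:3)
#' exceedance_proportion(hourly_series(ts, c(99, 105, 110, 99)), 100)
#' @export
exceedance_proportion <- function(series, threshold = 100) {
  if (nrow(series) == 0L) stop("empty series", call. = FALSE)
  ok <- !is.na(series$api)
  if (!any(ok)) stop("all values missing", call. = FALSE)
  mean(series$api[ok] > threshold)
}
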