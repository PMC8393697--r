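test_that("event extraction reproduces hand-enumerated runs and sums", {
  cat0 <- extract_events(series_of(c(99, 105, 110, 99, 101, 102, 100)))
  expect_equal(nrow(cat0), 2L)
  expect_equal(cat0$duration_hours, c(2L, 2L))
  expect_equal(cat0$severity, c(215, 203))
  expect_false(any(cat0$censored_end))

  # value exactly at the threshold is not unhealthy
  expect_equal(nrow(extract_events(series_of(c(100, 100, 99)))), 0L)

  # single-point run touching the record end is censored
  cat1 <- extract_events(series_of(101))
  expect_equal(cat1$duration_hours, 1L)
  expect_equal(cat1$severity, 101)
  expect_true(cat1$censored_end)
  expect_equal(nrow(extract_events(series_of(101), include_censored = FALSE)),
               0L)

  # all healthy -> empty catalog
  expect_equal(nrow(extract_events(series_of(c(50, 80, 100)))), 0L)
})

test_that("extraction validates its inputs", {
  expect_error(hourly_series(character(0), numeric(0)), "empty")
  expect_error(series_of(c(50, -3, 60)), "nonnegative")
  expect_error(
    hourly_series(as.POSIXct("2019-01-01", tz = "UTC") + c(0, 3600, 3600),
                  c(1, 2, 3)),
    "increasing")
})

test_that("missing values break or bridge runs, never silently vanish", {
  v <- c(99, 120, 130, NA, 140, 150, 99)
  # break: the NA terminates the first run
  cb <- extract_events(series_of(v), missing_policy = "break")
  expect_equal(cb$duration_hours, c(2L, 2L))
  expect_equal(cb$severity, c(250, 290))
  # bridge: one missing hour inside a run is skipped, contributing nothing
  cg <- extract_events(series_of(v), missing_policy = "bridge", bridge_k = 1)
  expect_equal(cg$duration_hours, 4L)
  expect_equal(cg$severity, 540)
  # a missing stretch longer than bridge_k still breaks
  v2 <- c(99, 120, NA, NA, 140, 99)
  cg2 <- extract_events(series_of(v2), missing_policy = "bridge", bridge_k = 1)
  expect_equal(cg2$duration_hours, c(1L, 1L))
  # missing at the run edge (not flanked) is never bridged
  v3 <- c(NA, 120, 130, 99)
  cg3 <- extract_events(series_of(v3), missing_policy = "bridge", bridge_k = 2)
  expect_equal(cg3$duration_hours, 2L)
})

test_that("a timestamp gap terminates an open run", {
  ts <- as.POSIXct("2019-01-01", tz = "UTC") + 3600 * c(0, 1, 5, 6)
  s <- hourly_series(ts, c(120, 130, 140, 99), quiet = TRUE)
  expect_equal(attr(s, "n_gaps"), 3)
  cat2 <- extract_events(s)
  expect_equal(cat2$duration_hours, c(2L, 1L))
  expect_equal(cat2$severity, c(250, 140))
})

test_that("total duration equals the exceedance-hour count (conservation)", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- round(stats::rlnorm(2000, log(60), 0.5))
    s <- series_of(v)
    cat3 <- extract_events(s)
    expect_identical(sum(cat3$duration_hours), sum(v > 100))
    expect_true(all(cat3$severity >= 101 * cat3$duration_hours))
    # exceedance proportion agrees with the direct count
    expect_equal(exceedance_proportion(s), mean(v > 100))
  }
})

test_that("re-extraction from a reconstructed series is idempotent", {
  set.seed(42)
  v <- round(stats::rlnorm(3000, log(70), 0.45))
  cat4 <- extract_events(series_of(v))
  expect_gt(nrow(cat4), 2)
  # rebuild: runs of the catalog separated by sub-threshold filler
  rebuilt <- numeric(0)
  set.seed(43)
  for (i in seq_len(nrow(cat4))) {
    d <- cat4$duration_hours[i]
    # spread severity over the run, integer-valued, each hour > 100
    run <- rep(floor(cat4$severity[i] / d), d)
    run[1] <- run[1] + cat4$severity[i] - sum(run)
    rebuilt <- c(rebuilt, run, 50)
  }
  cat5 <- extract_events(series_of(rebuilt))
  expect_equal(cat5$duration_hours, cat4$duration_hours)
  expect_equal(cat5$severity, cat4$severity)
})

test_that("mean inter-arrival time is the mean start-to-start gap in days", {
  v <- rep(50, 100)
  v[c(1, 49, 97)] <- 150
  cat6 <- extract_events(series_of(v))
  expect_equal(mean_interarrival_days(cat6), 2)

  v2 <- rep(50, 30); v2[c(1, 25)] <- 150
  expect_equal(mean_interarrival_days(extract_events(series_of(v2))), 1)

  expect_error(mean_interarrival_days(extract_events(series_of(101))),
               "undefined")
})

test_that("summary statistics follow the fixed conventions", {
  s <- summary_stats(c(1, 2, 3, 10))
  expect_equal(s$mean, 4)
  expect_equal(s$median, 2.5)
  # constant vector: sd 0, skewness 0 by convention
  s0 <- summary_stats(rep(5, 4))
  expect_equal(s0$sd, 0)
  expect_equal(s0$skewness, 0)
  expect_equal(s0$kurtosis, 3)  # raw kurtosis convention
  expect_error(summary_stats(numeric(0)), "empty")
  # large symmetric sample: skewness within 3 standard errors of 0
  set.seed(7)
  x <- stats::rnorm(4000)
  se <- sqrt(6 / length(x))
  expect_lt(abs(summary_stats(x)$skewness), 3 * se)
  # raw kurtosis of a normal sample is near 3
  expect_equal(summary_stats(x)$kurtosis, 3, tolerance = 0.15)
})

test_that("exceedance proportion handles boundary cases", {
  expect_equal(exceedance_proportion(series_of(c(99, 105, 110, 99)), 100), 0.5)
  expect_equal(exceedance_proportion(series_of(c(10, 20)), 100), 0)
  expect_equal(exceedance_proportion(series_of(c(110, 120)), 100), 1)
  expect_error(exceedance_proportion(series_of(c(NA, NA))), "missing")
})

test_that("catalogs round-trip through CSV", {
  cat7 <- extract_events(series_of(c(99, 105, 110, 99, 101, 102, 100)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_catalog(cat7, path)
  back <- read_event_catalog(path)
  expect_equal(back$duration_hours, cat7$duration_hours)
  expect_equal(back$severity, cat7$severity)
  expect_equal(as.numeric(back$start), as.numeric(cat7$start))
})
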