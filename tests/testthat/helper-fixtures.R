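# shared fixtures: tiny series builders and an independently-coded Clayton
# density used as an oracle in fit tests

hours_from <- function(n, origin = "2019-01-01") {
  as.POSIXct(origin, tz = "UTC") + 3600 * (seq_len(n) - 1)
}

series_of <- function(values, origin = "2019-01-01") {
  hourly_series(hours_from(length(values), origin), values, quiet = TRUE)
}

# representative theta grids per family (moderate through strong dependence)
theta_grid <- function(family) {
  switch(family,
    clayton = c(0.5, 2, 8, 22.85),
    amh = c(-0.9, -0.3, 0.4, 0.95),
    frank = c(-20, -3, 0.5, 8, 48),
    plackett = c(0.05, 0.5, 4, 80, 846.5),
    gumbel_hougaard = c(1.2, 2.5, 6, 12.42),
    joe = c(1.3, 3, 8, 25.38))
}

all_families <- c("clayton", "amh", "frank", "plackett",
                  "gumbel_hougaard", "joe")

# Clayton log-density written directly from the textbook formula (no shared
# code with the package's log-space evaluator); oracle for fit tests
clayton_logpdf_naive <- function(u1, u2, th) {
  log((th + 1) * (u1 * u2)^(-th - 1) *
        (u1^(-th) + u2^(-th) - 1)^(-(1 / th) - 2))
}
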