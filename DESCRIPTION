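Package: aircopula
Title: Copula Modelling of Duration and Severity of Unhealthy Air Pollution Episodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising unhealthy air-pollution episodes from an
    hourly air-quality-index series. Extracts threshold-exceedance events and
    their duration (consecutive unhealthy hours) and severity (cumulative index
    over the event), models the joint duration-severity distribution with six
    bivariate copula families (Clayton, Ali-Mikhail-Haq, Frank, Plackett,
    Gumbel-Hougaard, Joe) estimated by rank-based pseudo-maximum-likelihood,
    selects among families by a leave-one-out cross-validated copula
    information criterion, and derives copula-based risk measures: conditional
    severity probabilities and joint (OR/AND) and conditional return periods.
    Includes a synthetic-data generator emulating episodic exceedance series
    with strongly dependent, right-skewed duration-severity pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    fitdistrplus,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
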