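## Rank-based pseudo-observations, the nonparametric empirical margin used
## by the copula pipeline, parametric marginal fits kept as diagnostics, and
## Kolmogorov-Smirnov goodness of fit.

.MARGIN_FAMILIES <- c("exponential", "gamma", "lognormal", "weibull")

#' Rank-based pseudo-observations
#'
#' Transforms a sample to \eqn{\mathrm{rank}_i/(n+1)}, with average (mid)
#' ranks for ties, giving values strictly inside \eqn{(0, 1)} with maximum
#' \eqn{n/(n+1)}. Invariant under any strictly increasing transform of `x`.
#'
#' @param x Numeric vector, nonempty.
#' @return Numeric vector of pseudo-observations in \eqn{(0, 1)}.
#' @examples
#' pseudo_observations(c(3, 1, 2))   # 0.75 0.25 0.50
#' pseudo_observations(c(1, 1, 2))   # average ranks: 0.375 0.375 0.75
#' @export
pseudo_observations <- function(x) {
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  if (anyNA(x)) stop("missing values not allowed", call. = FALSE)
  rank(x, ties.method = "average") / (length(x) + 1)
}

#' Paired pseudo-observations of a catalog
#'
#' Applies [pseudo_observations()] to the duration and severity columns of
#' an event catalog, preserving the pairing.
#'
#' @param catalog An [extract_events()] catalog.
#' @return A list of class `"pseudo_sample"` with elements `u1` (duration),
#'   `u2` (severity), `n`.
#' @export
pseudo_sample <- function(catalog) {
  stopifnot(nrow(catalog) >= 1L)
  structure(list(u1 = pseudo_observations(catalog$duration_hours),
                 u2 = pseudo_observations(catalog$severity),
                 n = nrow(catalog)),
            class = "pseudo_sample")
}

#' Scaled empirical distribution function
#'
#' Returns the empirical CDF with denominator \eqn{n + 1}:
#' \eqn{\hat F(t) = \sum_j \mathbf{1}(x_j \le t)/(n+1)}, a right-continuous
#' step function that never reaches 1 (maximum \eqn{n/(n+1)}), keeping
#' copula densities evaluated at transformed data finite.
#'
#' @param x Numeric sample, nonempty.
#' @return A function of one argument `t`, vectorised.
#' @examples
#' F <- empirical_cdf(c(1, 2, 3))
#' F(c(0, 2, 10))  # 0.00 0.50 0.75
#' @export
empirical_cdf <- function(x) {
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  x <- sort(x[!is.na(x)])
  n <- length(x)
  function(t) findInterval(t, x) / (n + 1)
}

#' Parametric marginal fit
#'
#' Maximum-likelihood fit of one of four right-skewed families to strictly
#' positive data: exponential and lognormal in closed form, gamma and
#' Weibull numerically from a moment-based start (via
#' [fitdistrplus::fitdist()]).
#'
#' @param x Strictly positive numeric vector, length at least 3.
#' @param family One of `"exponential"`, `"gamma"`, `"lognormal"`,
#'   `"weibull"`.
#' @return An object of class `"margin_fit"`: list with `family`, `params`
#'   (named numeric), `loglik`, `n`, plus `cdf`/`density` closures.
#' @examples
#' fit_margin(c(1, 2, 3), "exponential")$params  # rate = 1/2
#' @export
fit_margin <- function(x, family = .MARGIN_FAMILIES) {
  family <- match.arg(family)
  x <- as.numeric(x)
  if (anyNA(x)) stop("missing values not allowed", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (any(x <= 0)) stop("data must be strictly positive", call. = FALSE)
  n <- length(x)
  if (family == "exponential") {
    rate <- 1 / mean(x)
    params <- c(rate = rate)
    loglik <- sum(stats::dexp(x, rate, log = TRUE))
  } else if (family == "lognormal") {
    meanlog <- mean(log(x))
    sdlog <- sqrt(mean((log(x) - meanlog)^2))  # MLE: population sd of logs
    if (sdlog == 0) stop("degenerate data: all values equal", call. = FALSE)
    params <- c(meanlog = meanlog, sdlog = sdlog)
    loglik <- sum(stats::dlnorm(x, meanlog, sdlog, log = TRUE))
  } else {
    ## fit on mean-scaled data (both families are scale-equivariant) so the
    ## optimizer sees O(1) magnitudes whatever the units of x
    cs <- mean(x)
    y <- x / cs
    m <- mean(y); v <- stats::var(y)
    if (v == 0) stop("degenerate data: all values equal", call. = FALSE)
    start <- if (family == "gamma") {
      list(shape = m^2 / v, rate = m / v)
    } else {
      ## Weibull moment start: crude shape from CV, scale from mean
      cv <- sqrt(v) / m
      k0 <- max(0.1, cv^(-1.086))   # Justus approximation
      list(shape = k0, scale = m / gamma(1 + 1 / k0))
    }
    fd <- tryCatch(
      fitdistrplus::fitdist(y, family, start = start),
      error = function(e) stop(sprintf("%s MLE failed to converge: %s",
                                       family, conditionMessage(e)),
                               call. = FALSE))
    params <- fd$estimate
    if (family == "gamma") {
      params[["rate"]] <- params[["rate"]] / cs
      loglik <- sum(stats::dgamma(x, params[["shape"]], params[["rate"]],
                                  log = TRUE))
    } else {
      params[["scale"]] <- params[["scale"]] * cs
      loglik <- sum(stats::dweibull(x, params[["shape"]], params[["scale"]],
                                    log = TRUE))
    }
  }
  pfun <- switch(family,
    exponential = function(q) stats::pexp(q, params[["rate"]]),
    gamma = function(q) stats::pgamma(q, params[["shape"]], params[["rate"]]),
    lognormal = function(q) stats::plnorm(q, params[["meanlog"]],
                                          params[["sdlog"]]),
    weibull = function(q) stats::pweibull(q, params[["shape"]],
                                          params[["scale"]]))
  dfun <- switch(family,
    exponential = function(q) stats::dexp(q, params[["rate"]]),
    gamma = function(q) stats::dgamma(q, params[["shape"]], params[["rate"]]),
    lognormal = function(q) stats::dlnorm(q, params[["meanlog"]],
                                          params[["sdlog"]]),
    weibull = function(q) stats::dweibull(q, params[["shape"]],
                                          params[["scale"]]))
  structure(list(family = family, params = params, loglik = loglik, n = n,
                 cdf = pfun, density = dfun),
            class = "margin_fit")
}

#' @export
print.margin_fit <- function(x, ...) {
  cat(sprintf("<margin_fit> %s: %s | loglik %.2f (n = %d)\n", x$family,
              paste(names(x$params), signif(x$params, 5), sep = " = ",
                    collapse = ", "),
              x$loglik, x$n))
  invisible(x)
}

#' Kolmogorov-Smirnov goodness of fit for a marginal fit
#'
#' One-sample KS test of the data against the fitted CDF,
#' \eqn{\sup_t |F_n(t) - F_{fit}(t)|}, with the asymptotic Kolmogorov
#' p-value. The parameters were estimated from the same data, which makes
#' the nominal p-value conservative-to-invalid in the usual way
#' (no Lilliefors-type correction is applied); treat it as a descriptive
#' index of fit rather than an exact test. Integer-valued durations always
#' carry ties, so the ties warning from [stats::ks.test()] is suppressed.
#'
#' @param x Numeric sample the fit was obtained from.
#' @param fit A [fit_margin()] object.
#' @return A list of class `"gof_result"` with `ks_statistic` and `p_value`.
#' @export
ks_gof <- function(x, fit) {
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  stopifnot(inherits(fit, "margin_fit"))
  kt <- suppressWarnings(stats::ks.test(x, fit$cdf, exact = FALSE))
  structure(list(ks_statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value)),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("<gof_result> KS statistic %.4f, p-value %.4g\n",
              x$ks_statistic, x$p_value))
  invisible(x)
}

#' Marginal goodness-of-fit report for a catalog
#'
#' Fits each requested family to the duration and severity margins of a
#' catalog and tabulates the KS statistic and p-value for each, one row per
#' (variable, family).
#'
#' @param catalog An [extract_events()] catalog.
#' @param families Subset of `"exponential"`, `"gamma"`, `"lognormal"`,
#'   `"weibull"`.
#' @return A data frame with columns `variable`, `family`, `ks_statistic`,
#'   `p_value`, `loglik`.
#' @export
margin_gof_table <- function(catalog, families = .MARGIN_FAMILIES) {
  families <- match.arg(families, several.ok = TRUE)
  vars <- list(duration = catalog$duration_hours, severity = catalog$severity)
  rows <- list()
  for (v in names(vars)) {
    for (f in families) {
      fit <- fit_margin(vars[[v]], f)
      g <- ks_gof(vars[[v]], fit)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, family = f, ks_statistic = g$ks_statistic,
        p_value = g$p_value, loglik = fit$loglik)
    }
  }
  do.call(rbind, rows)
}
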