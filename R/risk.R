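## Copula-based risk measures: conditional severity probability, joint
## (OR/AND) and conditional return periods, and Table-style report grids.

#' Conditional probability of severity given duration exceedance
#'
#' Computes \eqn{P(S \le s \mid D \ge d') = (u_2 - C(u_1', u_2))/(1 - u_1')}
#' on the uniform scale, where \eqn{u_1' = F_D(d')} and
#' \eqn{u_2 = F_S(s)}. A valid CDF in `u2`: 0 at 0, 1 at 1, nondecreasing;
#' equal to `u2` under independence.
#'
#' @param spec A [copula_spec()].
#' @param u1_prime Conditioning level \eqn{F_D(d')}, strictly below 1.
#' @param u2 Severity level(s) \eqn{F_S(s)} in \eqn{[0, 1]}.
#' @return Probabilities in \eqn{[0, 1]}.
#' @examples
#' conditional_prob(copula_spec("joe", 25.38), 0.89, 0.90)
#' @export
conditional_prob <- function(spec, u1_prime, u2) {
  .check_spec(spec)
  stopifnot(length(u1_prime) == 1L, u1_prime >= 0)
  if (u1_prime >= 1) {
    stop("u1_prime must be < 1: conditioning event D >= d' has probability 0",
         call. = FALSE)
  }
  out <- (u2 - copula_cdf(spec, u1_prime, u2)) / (1 - u1_prime)
  pmin(pmax(out, 0), 1)
}

#' Joint and conditional return periods
#'
#' The four copula-based recurrence horizons for the bivariate exceedance
#' of a duration level \eqn{d} and severity level \eqn{s}, in days, given
#' the marginal probabilities \eqn{F_D(d)} and \eqn{F_S(s)} and the mean
#' event inter-arrival time \eqn{E(L)}:
#' \deqn{T'_{DS} = E(L) / (1 - C),\quad
#'       T_{DS} = E(L) / (1 - F_D - F_S + C),}
#' \deqn{T_{D|S \ge s} = E(L) / [(1 - F_S)(1 - F_D - F_S + C)],\quad
#'       T_{S|D \ge d} = E(L) / [(1 - F_D)(1 - F_D - F_S + C)],}
#' with \eqn{C = C(F_D(d), F_S(s))}. \eqn{T'_{DS}} is the OR horizon
#' (either exceeds), \eqn{T_{DS}} the AND horizon (both exceed); the
#' conditional horizons retain the \eqn{E(L)} factor so all four carry time
#' units. Always \eqn{T'_{DS} \le T_{DS} \le} both conditional horizons.
#'
#' @param spec A [copula_spec()].
#' @param f_d,f_s Marginal nonexceedance probabilities \eqn{F_D(d)},
#'   \eqn{F_S(s)}, each in \eqn{[0, 1)}.
#' @param el_days Mean inter-arrival time between events, in days
#'   (see [mean_interarrival_days()]); must be positive.
#' @return An object of class `"return_period_set"`: list with `t_or`,
#'   `t_and`, `t_d_given_s`, `t_s_given_d`, `el_days` (all days).
#' @examples
#' return_periods(copula_spec("frank", 1e-8), 0.5, 0.5, el_days = 1)
#' @export
return_periods <- function(spec, f_d, f_s, el_days) {
  .check_spec(spec)
  stopifnot(length(f_d) == 1L, length(f_s) == 1L, length(el_days) == 1L)
  if (el_days <= 0) stop("el_days must be positive", call. = FALSE)
  if (f_d < 0 || f_s < 0 || f_d >= 1 || f_s >= 1) {
    stop("f_d and f_s must lie in [0, 1): a marginal probability of 1 gives an infinite return period",
         call. = FALSE)
  }
  C <- copula_cdf(spec, f_d, f_s)
  p_and <- 1 - f_d - f_s + C       # P(D >= d and S >= s)
  p_or <- 1 - C                    # P(D >= d or S >= s)
  structure(list(t_or = el_days / p_or,
                 t_and = el_days / p_and,
                 t_d_given_s = el_days / ((1 - f_s) * p_and),
                 t_s_given_d = el_days / ((1 - f_d) * p_and),
                 el_days = el_days),
            class = "return_period_set")
}

#' @export
print.return_period_set <- function(x, ...) {
  cat(sprintf(
    "<return_period_set> OR %.1f d | AND %.1f d | D|S %.1f d | S|D %.1f d (E(L) = %.2f d)\n",
    x$t_or, x$t_and, x$t_d_given_s, x$t_s_given_d, x$el_days))
  invisible(x)
}

#' Empirical margin evaluator for a catalog
#'
#' Maps physical duration (hours) and severity values to marginal
#' probabilities through the scaled empirical CDFs ([empirical_cdf()],
#' denominator \eqn{n+1}) of the catalog, the same margins the copula
#' pipeline is fitted on. Values never reach 1, keeping return periods
#' finite.
#'
#' @param catalog An [extract_events()] catalog.
#' @return An object of class `"margin_evaluator"`: list with functions
#'   `cdf_d`, `cdf_s` and `source = "empirical"`.
#' @export
empirical_margins <- function(catalog) {
  stopifnot(nrow(catalog) >= 1L)
  structure(list(cdf_d = empirical_cdf(catalog$duration_hours),
                 cdf_s = empirical_cdf(catalog$severity),
                 source = "empirical"),
            class = "margin_evaluator")
}

#' Return-period table over a duration-severity grid
#'
#' Evaluates [return_periods()] for every combination of the requested
#' duration and severity levels, mapping the physical levels to marginal
#' probabilities through `margins`.
#'
#' @param spec A [copula_spec()] (typically the selected fit).
#' @param margins A [empirical_margins()] evaluator (or any list with
#'   functions `cdf_d`, `cdf_s`).
#' @param el_days Mean inter-arrival time in days.
#' @param d_list Duration levels (hours).
#' @param s_list Severity levels.
#' @return A data frame with columns `duration`, `severity`, `t_or_days`,
#'   `t_and_days`, `t_d_given_s_days`, `t_s_given_d_days`; one row per
#'   (duration, severity) pair, severity varying fastest.
#' @export
risk_table <- function(spec, margins, el_days, d_list, s_list) {
  .check_spec(spec)
  stopifnot(length(d_list) >= 1L, length(s_list) >= 1L)
  rows <- list()
  for (d in d_list) {
    f_d <- margins$cdf_d(d)
    for (s in s_list) {
      f_s <- margins$cdf_s(s)
      rp <- return_periods(spec, f_d, f_s, el_days)
      rows[[length(rows) + 1L]] <- data.frame(
        duration = d, severity = s,
        t_or_days = rp$t_or, t_and_days = rp$t_and,
        t_d_given_s_days = rp$t_d_given_s,
        t_s_given_d_days = rp$t_s_given_d)
    }
  }
  do.call(rbind, rows)
}
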