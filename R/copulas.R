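## Six one-parameter bivariate copula families used throughout the package.
## All evaluators are vectorised over (u1, u2) and guard the near-singular
## parameter values (Frank theta ~ 0, Plackett theta ~ 1, Clayton theta ~ 0)
## by switching to the independence limit.

.COPULA_FAMILIES <- c("clayton", "amh", "frank", "plackett",
                      "gumbel_hougaard", "joe")

## below this, Frank/Clayton theta and Plackett |theta - 1| are treated as
## the independence limit
.IND_EPS <- 1e-6

#' Bivariate copula specification
#'
#' Constructs a validated copula specification: a family tag plus its
#' dependence parameter \eqn{\theta}. The admissible parameter spaces are
#' \describe{
#'   \item{clayton}{\eqn{\theta > 0}; \eqn{\theta \to 0} is the independence
#'     limit (values below \code{1e-6} are evaluated as independence).}
#'   \item{amh}{Ali--Mikhail--Haq, \eqn{-1 \le \theta < 1}; \eqn{\theta = 1}
#'     is admitted as the boundary limit (Kendall's tau \eqn{\to 1/3}).}
#'   \item{frank}{\eqn{\theta \ne 0} real; \eqn{\theta \to 0} independence
#'     limit.}
#'   \item{plackett}{\eqn{\theta > 0}; \eqn{\theta = 1} is independence.}
#'   \item{gumbel_hougaard}{\eqn{\theta \ge 1}; \eqn{\theta = 1} is
#'     independence.}
#'   \item{joe}{\eqn{\theta \ge 1}; \eqn{\theta = 1} is independence.}
#' }
#'
#' @param family One of `"clayton"`, `"amh"`, `"frank"`, `"plackett"`,
#'   `"gumbel_hougaard"`, `"joe"`. `"gumbel"` is accepted as an alias for
#'   `"gumbel_hougaard"`.
#' @param theta Numeric scalar dependence parameter.
#' @return An object of class `"copula_spec"`: a list with elements `family`
#'   and `theta`.
#' @examples
#' copula_spec("clayton", 2)
#' copula_spec("joe", 25.38)
#' @export
copula_spec <- function(family, theta) {
  if (identical(family, "gumbel")) family <- "gumbel_hougaard"
  family <- match.arg(family, .COPULA_FAMILIES)
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta))
  ok <- switch(family,
    clayton          = theta >= 0,
    amh              = theta >= -1 && theta <= 1,
    frank            = TRUE,
    plackett         = theta > 0,
    gumbel_hougaard  = theta >= 1,
    joe              = theta >= 1)
  if (!ok) {
    stop(sprintf("theta = %g is outside the parameter space of the %s copula",
                 theta, family), call. = FALSE)
  }
  structure(list(family = family, theta = theta), class = "copula_spec")
}

#' @export
print.copula_spec <- function(x, ...) {
  cat(sprintf("<copula_spec> %s copula, theta = %g (Kendall's tau = %.4f)\n",
              x$family, x$theta, kendall_tau(x)))
  invisible(x)
}

.check_spec <- function(spec) {
  if (!inherits(spec, "copula_spec")) {
    stop("`spec` must be a copula_spec object", call. = FALSE)
  }
  spec
}

## log(exp(a) + exp(b) - 1) for a, b >= 0, computed stably
.log_sum_m1 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m) - exp(-m))
}

## Frank copula workhorse: log|D| with
##   D = e^{-th u1} + e^{-th u2} - e^{-th(u1+u2)} - e^{-th}.
## D > 0 for th > 0 and D < 0 for th < 0; it enters the CDF as
## C = -(1/th)(log|D| - log|1 - e^{-th}|), the h-function as
## h = e^{-th u1}(1 - e^{-th u2})/D, and the density squared. Direct use of
## expm1 products loses all precision once |th| u approaches 40.
.frank_logabsD <- function(th, u1, u2) {
  e1 <- -th * u1; e2 <- -th * u2; e3 <- e1 + e2; e4 <- rep_len(-th, length(e1))
  m <- pmax(e1, e2, e3, e4)
  m + log(abs(exp(e1 - m) + exp(e2 - m) - exp(e3 - m) - exp(e4 - m)))
}

## log|1 - e^{-th}|
.frank_log1me <- function(th) {
  if (th > 0) log1p(-exp(-th)) else -th + log1p(-exp(th))
}

## Joe copula workhorse: log T with T = a + b - ab, a = (1-u1)^theta,
## b = (1-u2)^theta, given la = log a, lb = log b (both <= 0). The
## log-sum-exp form stays accurate at both corners of the unit square,
## where the naive 1 - (1-a)(1-b) loses all precision (a, b -> 0).
.joe_logT <- function(la, lb) {
  m <- pmax(la, lb)
  m + log(exp(la - m) + exp(lb - m) - exp(la + lb - m))
}

#' Copula cumulative distribution function
#'
#' Evaluates \eqn{C(u_1, u_2; \theta)} for the specified family. Boundary
#' identities \eqn{C(u, 0) = 0} and \eqn{C(u, 1) = u} hold exactly, and the
#' value always lies within the Frechet--Hoeffding bounds
#' \eqn{\max(u_1 + u_2 - 1, 0) \le C \le \min(u_1, u_2)}.
#'
#' @param spec A [copula_spec()].
#' @param u1,u2 Numeric vectors in \eqn{[0, 1]} (recycled to common length).
#' @return Numeric vector of copula CDF values.
#' @examples
#' copula_cdf(copula_spec("clayton", 2), 0.5, 0.5) # 7^(-1/2)
#' @export
copula_cdf <- function(spec, u1, u2) {
  .check_spec(spec)
  n <- max(length(u1), length(u2))
  u1 <- rep_len(as.numeric(u1), n); u2 <- rep_len(as.numeric(u2), n)
  if (any(u1 < 0 | u1 > 1 | u2 < 0 | u2 > 1, na.rm = TRUE)) {
    stop("u1 and u2 must lie in [0, 1]", call. = FALSE)
  }
  th <- spec$theta
  ## interior points only; boundaries patched exactly below
  int <- u1 > 0 & u1 < 1 & u2 > 0 & u2 < 1
  a1 <- u1[int]; a2 <- u2[int]
  val <- switch(spec$family,
    clayton = {
      if (th < .IND_EPS) a1 * a2 else {
        exp(-.log_sum_m1(-th * log(a1), -th * log(a2)) / th)
      }
    },
    amh = a1 * a2 / (1 - th * (1 - a1) * (1 - a2)),
    frank = {
      if (abs(th) < .IND_EPS) a1 * a2 else {
        -(.frank_logabsD(th, a1, a2) - .frank_log1me(th)) / th
      }
    },
    plackett = {
      if (abs(th - 1) < .IND_EPS) a1 * a2 else {
        L <- 1 + (th - 1) * (a1 + a2)
        disc <- pmax(L^2 - 4 * th * (th - 1) * a1 * a2, 0)
        (L - sqrt(disc)) / (2 * (th - 1))
      }
    },
    gumbel_hougaard = {
      lx <- log(-log(a1)); ly <- log(-log(a2))
      m <- pmax(lx, ly)
      lvth <- th * m + log(exp(th * (lx - m)) + exp(th * (ly - m)))
      exp(-exp(lvth / th))
    },
    joe = {
      logT <- .joe_logT(th * log1p(-a1), th * log1p(-a2))
      -expm1(logT / th)
    })
  out <- numeric(n)
  out[int] <- pmin(pmax(val, 0), pmin(a1, a2))
  out[u1 == 0 | u2 == 0] <- 0
  i <- u2 == 1; out[i] <- u1[i]
  i <- u1 == 1; out[i] <- u2[i]
  out[u1 == 1 & u2 == 1] <- 1
  out
}

#' Copula density
#'
#' Evaluates the copula density \eqn{c(u_1, u_2; \theta) =
#' \partial^2 C / \partial u_1 \partial u_2} on the open unit square.
#' Computation is carried out in log space so that large dependence
#' parameters (e.g. Frank \eqn{\theta \approx 50}, Joe
#' \eqn{\theta \approx 25}) do not overflow.
#'
#' @inheritParams copula_cdf
#' @param log If `TRUE`, return the log density.
#' @return Numeric vector of (log) density values; densities are nonnegative.
#' @examples
#' copula_pdf(copula_spec("frank", 5), 0.3, 0.8)
#' @export
copula_pdf <- function(spec, u1, u2, log = FALSE) {
  .check_spec(spec)
  n <- max(length(u1), length(u2))
  u1 <- rep_len(as.numeric(u1), n); u2 <- rep_len(as.numeric(u2), n)
  if (any(u1 <= 0 | u1 >= 1 | u2 <= 0 | u2 >= 1)) {
    stop("copula density requires u1, u2 strictly inside (0, 1)",
         call. = FALSE)
  }
  th <- spec$theta
  ld <- switch(spec$family,
    clayton = {
      if (th < .IND_EPS) rep(0, n) else {
        lS <- .log_sum_m1(-th * log(u1), -th * log(u2))
        log1p(th) - (th + 1) * (log(u1) + log(u2)) - (1 / th + 2) * lS
      }
    },
    amh = {
      h <- 1 - th * (1 - u1) * (1 - u2)
      num <- 1 + th * (u1 + u2 + u1 * u2 - 2) -
        th^2 * (u1 + u2 - u1 * u2 - 1)
      log(num) - 3 * log(h)
    },
    frank = {
      if (abs(th) < .IND_EPS) rep(0, n) else {
        ## c = theta (1 - e^-theta) e^{-theta(u1+u2)} / D^2;
        ## theta (1 - e^-theta) > 0 for all theta != 0 and D enters squared,
        ## so absolute values under the logs are safe.
        lD <- .frank_logabsD(th, u1, u2)
        log(abs(th)) + .frank_log1me(th) - th * (u1 + u2) - 2 * lD
      }
    },
    plackett = {
      if (abs(th - 1) < .IND_EPS) rep(0, n) else {
        L <- 1 + (th - 1) * (u1 + u2)
        disc <- pmax(L^2 - 4 * th * (th - 1) * u1 * u2, 1e-300)
        log(th) + log1p((th - 1) * (u1 + u2 - 2 * u1 * u2)) -
          1.5 * log(disc)
      }
    },
    gumbel_hougaard = {
      lx <- log(-log(u1)); ly <- log(-log(u2))
      m <- pmax(lx, ly)
      lvth <- th * m + log(exp(th * (lx - m)) + exp(th * (ly - m)))
      -exp(lvth / th) + (th - 1) * (lx + ly) + (2 / th - 2) * lvth +
        log1p((th - 1) * exp(-lvth / th)) - log(u1) - log(u2)
    },
    joe = {
      logT <- .joe_logT(th * log1p(-u1), th * log1p(-u2))
      (1 / th - 2) * logT +
        (th - 1) * (log1p(-u1) + log1p(-u2)) +
        log(th - 1 + exp(logT))
    })
  if (log) ld else exp(ld)
}

#' Kendall's tau implied by a copula
#'
#' Returns the population Kendall's \eqn{\tau} for the family at its
#' parameter, using the closed form where one exists:
#' Clayton \eqn{\tau = \theta/(\theta+2)}; AMH
#' \eqn{\tau = (3\theta-2)/(3\theta) - 2(1-\theta)^2\log(1-\theta)/(3\theta^2)}
#' (limit \eqn{1/3} at \eqn{\theta = 1}); Frank
#' \eqn{\tau = 1 + 4(D_1(\theta)-1)/\theta} with Debye function
#' \eqn{D_1(\theta) = \theta^{-1}\int_0^\theta t/(e^t-1)\,dt};
#' Gumbel--Hougaard \eqn{\tau = 1 - 1/\theta}; Joe via the convergent series
#' \eqn{\tau = 1 - 4\sum_{k\ge1} [k(\theta k+2)(\theta(k-1)+2)]^{-1}}
#' truncated when terms fall below \code{1e-12}. The Plackett family has no
#' closed form and is evaluated by [tau_numeric()].
#'
#' @inheritParams copula_cdf
#' @return Kendall's tau in \eqn{[-1, 1]}.
#' @examples
#' kendall_tau(copula_spec("clayton", 22.85))
#' kendall_tau(copula_spec("amh", 1)) # boundary limit 1/3
#' @export
kendall_tau <- function(spec) {
  .check_spec(spec)
  th <- spec$theta
  switch(spec$family,
    clayton = th / (th + 2),
    amh = {
      if (abs(th) < 1e-5) {
        2 * th / 9                       # series limit near independence
      } else if (th >= 1 - 1e-12) {
        1 / 3                            # boundary limit: log term vanishes
      } else {
        (3 * th - 2) / (3 * th) -
          2 * (1 - th)^2 * log1p(-th) / (3 * th^2)
      }
    },
    frank = {
      if (abs(th) < .IND_EPS) return(0)
      if (th < 0) return(-kendall_tau(copula_spec("frank", -th)))
      1 + 4 * (.debye1(th) - 1) / th
    },
    plackett = as.numeric(tau_numeric(spec)),
    gumbel_hougaard = 1 - 1 / th,
    joe = {
      if (th == 1) return(0)
      k <- 1; s <- 0
      repeat {
        term <- 1 / (k * (th * k + 2) * (th * (k - 1) + 2))
        s <- s + term
        if (term < 1e-12) break
        k <- k + 1
      }
      1 - 4 * s
    })
}

## Debye function D1(x) = (1/x) int_0^x t/(e^t - 1) dt, x > 0.
## For x > 30 the integral to x equals pi^2/6 minus an exponentially small
## tail int_x^Inf t/(e^t-1) dt = sum_{k>=1} e^{-kx}(x/k + 1/k^2), of which
## the k = 1 term suffices (the next is < e^{-60}).
.debye1 <- function(x) {
  stopifnot(x > 0)
  if (x > 30) {
    (pi^2 / 6 - exp(-x) * (x + 1)) / x
  } else {
    I <- stats::integrate(function(t) ifelse(t == 0, 1, t / expm1(t)),
                          0, x, rel.tol = 1e-10)$value
    I / x
  }
}

#' Kendall's tau by numerical integration
#'
#' Evaluates \eqn{\tau = 4\int\!\!\int_{(0,1)^2} C(u_1,u_2)\,c(u_1,u_2)
#' \,du_1du_2 - 1} by tensor-product Gauss--Legendre quadrature, refining the
#' node count until successive estimates agree to `tol`. This is the primary
#' method for the Plackett family (which has no closed form) and serves as an
#' independent cross-check of the closed forms for the other families.
#'
#' @inheritParams copula_cdf
#' @param tol Convergence tolerance between successive refinements.
#' @return Kendall's tau; the converged node count is attached as attribute
#'   `"nodes"`.
#' @examples
#' tau_numeric(copula_spec("clayton", 2)) # ~ 0.5
#' @export
tau_numeric <- function(spec, tol = 1e-4) {
  .check_spec(spec)
  ## Nodes are Gauss-Legendre points pushed through the substitution
  ## u = (1 - cos(pi s))/2, which clusters them quadratically at both
  ## corners of (0,1): the tail-dependent families (Gumbel-Hougaard, Joe,
  ## Clayton at large theta) have densities diverging like (1-u)^{-1}
  ## along the diagonal corner, which plain Gauss-Legendre resolves
  ## too slowly.
  dense <- switch(spec$family,
                  plackett = spec$theta > 50 || spec$theta < 1 / 50,
                  gumbel_hougaard = ,
                  joe = spec$theta > 4,
                  clayton = spec$theta > 6,
                  frank = abs(spec$theta) > 15,
                  amh = FALSE)
  sizes <- if (dense) c(256L, 384L, 512L, 768L, 1024L)
           else c(64L, 128L, 256L, 384L, 512L)
  prev <- NA_real_
  for (nn in sizes) {
    gl <- pracma::gaussLegendre(nn, 0, 1)
    u <- (1 - cos(pi * gl$x)) / 2
    w <- gl$w * (pi / 2) * sin(pi * gl$x)
    U1 <- rep(u, times = nn)
    U2 <- rep(u, each = nn)
    M <- copula_cdf(spec, U1, U2) * copula_pdf(spec, U1, U2)
    est <- 4 * as.numeric(t(w) %*% matrix(M, nn, nn) %*% w) - 1
    if (!is.na(prev) && abs(est - prev) < tol) {
      return(structure(est, nodes = nn))
    }
    prev <- est
  }
  stop(sprintf(
    "tau quadrature did not converge to %g for %s copula (theta = %g)",
    tol, spec$family, spec$theta), call. = FALSE)
}

#' Dependence parameter from Kendall's tau
#'
#' Inverts the tau--theta relation of [kendall_tau()]: closed form for
#' Clayton (\eqn{\theta = 2\tau/(1-\tau)}) and Gumbel--Hougaard
#' (\eqn{\theta = 1/(1-\tau)}), a bracketing root search on a log scale
#' otherwise.
#'
#' @param family Copula family name (see [copula_spec()]).
#' @param tau Target Kendall's tau, inside the family's attainable range
#'   (AMH: \eqn{\tau \in (\tau_{min}, 1/3]} with
#'   \eqn{\tau_{min} = (5 - 8\log 2)/3 \approx -0.1817}; Clayton,
#'   Gumbel--Hougaard, Joe: \eqn{\tau \in (0, 1)}; Frank and Plackett: any
#'   \eqn{\tau \in (-1, 1)}).
#' @return The dependence parameter \eqn{\theta} such that
#'   `kendall_tau(copula_spec(family, theta))` equals `tau` to within
#'   \code{1e-4}.
#' @examples
#' theta_from_tau("clayton", 0.9195) # ~ 22.85
#' @export
theta_from_tau <- function(family, tau) {
  if (identical(family, "gumbel")) family <- "gumbel_hougaard"
  family <- match.arg(family, .COPULA_FAMILIES)
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau))
  amh_min <- (5 - 8 * log(2)) / 3
  range_err <- function(lo, hi, hi_closed = FALSE) {
    stop(sprintf(
      "tau = %g is not attainable by the %s copula (attainable range: (%.4f, %.4f%s)",
      tau, family, lo, hi, if (hi_closed) "]" else ")"), call. = FALSE)
  }
  switch(family,
    clayton = {
      if (tau <= 0 || tau >= 1) range_err(0, 1)
      2 * tau / (1 - tau)
    },
    gumbel_hougaard = {
      if (tau < 0 || tau >= 1) range_err(0, 1)
      1 / (1 - tau)
    },
    amh = {
      if (tau > 1 / 3 || tau <= amh_min) range_err(amh_min, 1 / 3, TRUE)
      if (abs(tau - 1 / 3) < 1e-12) return(1)
      .tau_root("amh", tau, lo = -1 + 1e-9, hi = 1 - 1e-9)
    },
    frank = {
      if (abs(tau) >= 1) range_err(-1, 1)
      if (abs(tau) < 1e-10) return(1e-10)
      sign(tau) * exp(.tau_root("frank", abs(tau),
                                lo = log(1e-5), hi = log(1e4),
                                transform = exp))
    },
    plackett = {
      if (abs(tau) >= 1) range_err(-1, 1)
      if (abs(tau) < 1e-10) return(1)
      ## quadrature resolves theta down to ~2e-3 (tau ~ -0.88); stronger
      ## negative dependence than that is out of practical reach here
      exp(.tau_root("plackett", tau, lo = log(2e-3), hi = log(2e4),
                    transform = exp, extend = TRUE))
    },
    joe = {
      if (tau < 0 || tau >= 1) range_err(0, 1)
      if (tau == 0) return(1)
      1 + exp(.tau_root("joe", tau, lo = -20, hi = log(1e4),
                        transform = function(t) 1 + exp(t)))
    })
}

## bracketing root of kendall_tau(transform(t)) = tau; `extend` allows
## upward extension of the bracket (tau is nondecreasing in theta for all
## families handled here)
.tau_root <- function(family, tau, lo, hi, transform = identity,
                      extend = FALSE) {
  f <- function(t) kendall_tau(copula_spec(family, transform(t))) - tau
  stats::uniroot(f, c(lo, hi), tol = 1e-10,
                 extendInt = if (extend) "upX" else "no")$root
}

#' Conditional distribution (h-function) of a copula
#'
#' Evaluates \eqn{h(u_2 \mid u_1) = \partial C(u_1, u_2)/\partial u_1}, the
#' conditional CDF of \eqn{U_2} given \eqn{U_1 = u_1}. Used for conditional
#' inversion sampling and as a finite-difference cross-check of the CDF.
#'
#' @inheritParams copula_cdf
#' @param u2 Evaluation points in \eqn{[0, 1]}.
#' @param given_u1 Conditioning value(s), strictly inside \eqn{(0, 1)}.
#' @return Values in \eqn{[0, 1]}, nondecreasing in `u2`, with
#'   \eqn{h(0\mid u_1)=0} and \eqn{h(1\mid u_1)=1}.
#' @examples
#' h_conditional(copula_spec("clayton", 2), 0.5, given_u1 = 0.5)
#' @export
h_conditional <- function(spec, u2, given_u1) {
  .check_spec(spec)
  n <- max(length(u2), length(given_u1))
  u2 <- rep_len(as.numeric(u2), n)
  u1 <- rep_len(as.numeric(given_u1), n)
  if (any(u1 <= 0 | u1 >= 1)) {
    stop("given_u1 must be strictly inside (0, 1)", call. = FALSE)
  }
  if (any(u2 < 0 | u2 > 1)) stop("u2 must lie in [0, 1]", call. = FALSE)
  ## interior evaluation; exact boundary patches below
  b0 <- u2 == 0; b1 <- u2 == 1
  u2i <- ifelse(b0 | b1, 0.5, u2)
  th <- spec$theta
  out <- switch(spec$family,
    clayton = {
      if (th < .IND_EPS) u2i else {
        lS <- .log_sum_m1(-th * log(u1), -th * log(u2i))
        exp(-(th + 1) * log(u1) - (1 / th + 1) * lS)
      }
    },
    amh = {
      h <- 1 - th * (1 - u1) * (1 - u2i)
      u2i * (1 - th * (1 - u2i)) / h^2
    },
    frank = {
      if (abs(th) < .IND_EPS) u2i else {
        ## h = e^{-th u1} (1 - e^{-th u2}) / D; the numerator and D carry the
        ## same sign for th < 0, so log|.| arithmetic applies throughout
        lnum <- -th * u1 + log(abs(expm1(-th * u2i)))
        exp(lnum - .frank_logabsD(th, u1, u2i))
      }
    },
    plackett = {
      if (abs(th - 1) < .IND_EPS) u2i else {
        L <- 1 + (th - 1) * (u1 + u2i)
        disc <- pmax(L^2 - 4 * th * (th - 1) * u1 * u2i, 1e-300)
        0.5 * (1 - (L - 2 * th * u2i) / sqrt(disc))
      }
    },
    gumbel_hougaard = {
      lx <- log(-log(u1)); ly <- log(-log(u2i))
      m <- pmax(lx, ly)
      lvth <- th * m + log(exp(th * (lx - m)) + exp(th * (ly - m)))
      exp(-exp(lvth / th) + (1 / th - 1) * lvth + (th - 1) * lx - log(u1))
    },
    joe = {
      la <- th * log1p(-u1); lb <- th * log1p(-u2i)
      logT <- .joe_logT(la, lb)
      ## dC/du1 = T^(1/theta - 1) (1 - b) (1 - u1)^(theta - 1)
      exp((1 / th - 1) * logT + log(-expm1(lb)) + (th - 1) * log1p(-u1))
    })
  out[b0] <- 0
  out[b1] <- 1
  pmin(pmax(out, 0), 1)
}

## Vectorised bisection inverse of the h-function in u2: solves
## h(u2 | u1) = p. The h-function is a CDF in u2, hence nondecreasing; 64
## halvings of (0,1) reach machine precision.
.h_inverse <- function(spec, p, given_u1) {
  n <- max(length(p), length(given_u1))
  p <- rep_len(p, n); u1 <- rep_len(given_u1, n)
  lo <- rep(1e-12, n); hi <- rep(1 - 1e-12, n)
  for (i in seq_len(64L)) {
    mid <- 0.5 * (lo + hi)
    below <- h_conditional(spec, mid, u1) < p
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  0.5 * (lo + hi)
}

#' Sample dependent uniform pairs from a copula
#'
#' Draws `n` pairs \eqn{(u_1, u_2)} by conditional inversion: \eqn{u_1} and
#' \eqn{v} are independent uniforms and \eqn{u_2} solves
#' \eqn{h(u_2 \mid u_1) = v} by vectorised bisection. Reproducible given
#' `seed`.
#'
#' @inheritParams copula_cdf
#' @param n Number of pairs, at least 1.
#' @param seed Integer seed for the random draws.
#' @return A two-column matrix with columns `u1`, `u2`, values strictly
#'   inside \eqn{(0, 1)}.
#' @examples
#' head(sample_pairs(copula_spec("frank", 10), 5, seed = 1))
#' @export
sample_pairs <- function(spec, n, seed) {
  .check_spec(spec)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  set.seed(as.integer(seed))
  u1 <- stats::runif(n)
  v <- stats::runif(n)
  u2 <- .h_inverse(spec, v, u1)
  cbind(u1 = u1, u2 = u2)
}
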