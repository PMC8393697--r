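test_that("copula specifications validate their parameter spaces", {
  expect_error(copula_spec("clayton", -1), "outside")
  expect_error(copula_spec("amh", 1.5), "outside")
  expect_error(copula_spec("plackett", 0), "outside")
  expect_error(copula_spec("gumbel_hougaard", 0.5), "outside")
  expect_error(copula_spec("joe", 0.9), "outside")
  expect_equal(copula_spec("gumbel", 3)$family, "gumbel_hougaard")
})

test_that("CDF matches direct formula values and boundary identities", {
  expect_equal(copula_cdf(copula_spec("clayton", 2), 0.5, 0.5), 7^(-1 / 2),
               tolerance = 1e-12)
  # independence limits
  expect_equal(copula_cdf(copula_spec("frank", 1e-8), 0.3, 0.7), 0.21,
               tolerance = 1e-6)
  expect_equal(copula_cdf(copula_spec("plackett", 1 + 1e-8), 0.3, 0.7), 0.21,
               tolerance = 1e-6)
  # boundary identities for every family
  for (f in all_families) {
    for (th in theta_grid(f)) {
      s <- copula_spec(f, th)
      expect_equal(copula_cdf(s, 0.37, 1), 0.37)
      expect_equal(copula_cdf(s, 1, 0.81), 0.81)
      expect_equal(copula_cdf(s, 0.6, 0), 0)
      expect_equal(copula_cdf(s, 0, 0.6), 0)
    }
  }
})

test_that("CDF respects Frechet-Hoeffding bounds across parameter grids", {
  g <- seq(0.02, 0.98, length.out = 15)
  U1 <- rep(g, each = length(g)); U2 <- rep(g, times = length(g))
  lower <- pmax(U1 + U2 - 1, 0); upper <- pmin(U1, U2)
  for (f in all_families) {
    for (th in theta_grid(f)) {
      C <- copula_cdf(copula_spec(f, th), U1, U2)
      expect_true(all(C >= lower - 1e-12), label = paste(f, th, "lower"))
      expect_true(all(C <= upper + 1e-12), label = paste(f, th, "upper"))
    }
  }
})

test_that("CDF is 2-increasing on random rectangles", {
  set.seed(11)
  for (f in all_families) {
    for (th in theta_grid(f)) {
      s <- copula_spec(f, th)
      a1 <- stats::runif(50); b1 <- a1 + stats::runif(50) * (1 - a1)
      a2 <- stats::runif(50); b2 <- a2 + stats::runif(50) * (1 - a2)
      vol <- copula_cdf(s, b1, b2) - copula_cdf(s, a1, b2) -
        copula_cdf(s, b1, a2) + copula_cdf(s, a1, a2)
      expect_true(all(vol >= -1e-9), label = paste(f, th))
    }
  }
})

test_that("density agrees with the mixed finite difference of the CDF", {
  fd <- function(s, u, v, h = 1e-4) {
    (copula_cdf(s, u + h, v + h) - copula_cdf(s, u - h, v + h) -
       copula_cdf(s, u + h, v - h) + copula_cdf(s, u - h, v - h)) / (4 * h^2)
  }
  pts <- list(c(0.4, 0.6), c(0.2, 0.3), c(0.7, 0.75))
  for (f in all_families) {
    th <- switch(f, clayton = 3, amh = -0.6, frank = -7, plackett = 12,
                 gumbel_hougaard = 2.5, joe = 3)
    s <- copula_spec(f, th)
    for (p in pts) {
      expect_equal(copula_pdf(s, p[1], p[2]), fd(s, p[1], p[2]),
                   tolerance = 1e-4, label = paste(f, p[1], p[2]))
    }
  }
  # Joe at the stated point, against differentiation of its own CDF
  sj <- copula_spec("joe", 3)
  expect_equal(copula_pdf(sj, 0.4, 0.6), fd(sj, 0.4, 0.6, h = 1e-4),
               tolerance = 1e-5)
  # near-independent Frank density is ~1 on an interior grid
  g5 <- seq(0.1, 0.9, length.out = 5)
  dgrid <- copula_pdf(copula_spec("frank", 1e-8),
                      rep(g5, 5), rep(g5, each = 5))
  expect_true(all(abs(dgrid - 1) < 1e-4))
  expect_error(copula_pdf(sj, 0, 0.5), "inside")
})

test_that("densities integrate to 1 over the unit square", {
  gl <- pracma::gaussLegendre(256, 0, 1)
  u <- (1 - cos(pi * gl$x)) / 2
  w <- gl$w * (pi / 2) * sin(pi * gl$x)
  for (f in all_families) {
    th <- switch(f, clayton = 22.85, amh = 1 - 1e-6, frank = 48,
                 plackett = 846.5, gumbel_hougaard = 12.42, joe = 25.38)
    M <- copula_pdf(copula_spec(f, th), rep(u, times = 256),
                    rep(u, each = 256))
    I <- as.numeric(t(w) %*% matrix(M, 256, 256) %*% w)
    expect_equal(I, 1, tolerance = 1e-2, label = f)
  }
})

test_that("closed-form tau values match the published dependence strengths", {
  expect_equal(round(kendall_tau(copula_spec("clayton", 22.85)), 4), 0.9195)
  expect_equal(kendall_tau(copula_spec("gumbel_hougaard", 12.42)),
               1 - 1 / 12.42)
  expect_equal(round(kendall_tau(copula_spec("frank", 48)), 4), 0.9195)
  expect_equal(kendall_tau(copula_spec("amh", 1)), 1 / 3)
  expect_equal(kendall_tau(copula_spec("frank", 1e-9)), 0)
  # Joe series against the closed partial-fraction sum at theta = 2
  # series truncation at 1e-12 terms leaves an O(1e-8) tail
  expect_equal(kendall_tau(copula_spec("joe", 2)), 1 - (pi^2 / 6 - 1),
               tolerance = 1e-7)
  expect_equal(kendall_tau(copula_spec("joe", 1)), 0)
  # Frank tau is odd in theta
  expect_equal(kendall_tau(copula_spec("frank", -5)),
               -kendall_tau(copula_spec("frank", 5)))
})

test_that("numeric tau integration matches closed forms and Plackett values", {
  expect_equal(as.numeric(tau_numeric(copula_spec("clayton", 2))), 0.5,
               tolerance = 1e-3)
  expect_equal(as.numeric(tau_numeric(copula_spec("gumbel_hougaard", 4))),
               0.75, tolerance = 1e-3)
  # the strong-dependence Plackett value, converged to 4 decimals
  tp <- as.numeric(tau_numeric(copula_spec("plackett", 846.5), tol = 1e-5))
  expect_equal(tp, 0.9196, tolerance = 5e-5)
  # closed/series vs quadrature across the grids
  for (f in setdiff(all_families, "plackett")) {
    for (th in theta_grid(f)) {
      s <- copula_spec(f, th)
      expect_equal(as.numeric(tau_numeric(s)), kendall_tau(s),
                   tolerance = 1e-3, label = paste(f, th))
    }
  }
})

test_that("tau is nondecreasing in theta for the positively-ordered families", {
  grids <- list(clayton = c(0.2, 1, 3, 10, 30),
                frank = c(-30, -5, 1, 10, 60),
                gumbel_hougaard = c(1.1, 2, 5, 15),
                joe = c(1.1, 2, 5, 15, 40),
                plackett = c(0.1, 1.5, 10, 100, 1000))
  for (f in names(grids)) {
    taus <- vapply(grids[[f]],
                   function(th) as.numeric(kendall_tau(copula_spec(f, th))),
                   numeric(1))
    expect_true(all(diff(taus) > 0), label = f)
  }
})

test_that("theta_from_tau inverts kendall_tau (round trip)", {
  expect_equal(theta_from_tau("clayton", 0.9195), 22.85, tolerance = 1e-3)
  expect_equal(theta_from_tau("gumbel_hougaard", 0.9195), 12.42,
               tolerance = 1e-3)
  for (f in all_families) {
    for (th in theta_grid(f)) {
      if (f == "amh" && th > 0.9) next  # near-boundary: tau flat near 1/3
      tau0 <- as.numeric(kendall_tau(copula_spec(f, th)))
      th_back <- theta_from_tau(f, tau0)
      expect_equal(th_back, th, tolerance = 1e-3 * max(1, abs(th)),
                   label = paste(f, th))
    }
  }
  expect_error(theta_from_tau("amh", 0.9), "attainable")
  expect_error(theta_from_tau("clayton", -0.2), "attainable")
})

test_that("the conditional h-function behaves as a CDF and matches finite differences", {
  for (f in all_families) {
    th <- switch(f, clayton = 2, amh = 0.5, frank = 48, plackett = 50,
                 gumbel_hougaard = 3, joe = 25.38)
    s <- copula_spec(f, th)
    u2 <- seq(0, 1, length.out = 41)
    h <- h_conditional(s, u2, given_u1 = 0.55)
    expect_equal(h[1], 0)
    expect_equal(h[length(h)], 1)
    expect_true(all(diff(h) >= -1e-10), label = paste(f, "monotone"))
    # forward-difference of the CDF in u1
    d <- 1e-6
    fd <- (copula_cdf(s, 0.55 + d, 0.6) - copula_cdf(s, 0.55 - d, 0.6)) /
      (2 * d)
    expect_equal(h_conditional(s, 0.6, 0.55), fd, tolerance = 1e-4,
                 label = f)
  }
  expect_equal(h_conditional(copula_spec("frank", 1e-9), 0.7, 0.4), 0.7)
  expect_error(h_conditional(copula_spec("joe", 2), 0.5, 1), "inside")
})

test_that("conditional-inversion sampling reproduces the population tau", {
  p <- sample_pairs(copula_spec("clayton", 5), 5000, seed = 101)
  expect_true(all(p > 0 & p < 1))
  expect_equal(stats::cor(p[, 1], p[, 2], method = "kendall"), 5 / 7,
               tolerance = 0.03)
  p2 <- sample_pairs(copula_spec("frank", 1e-6), 5000, seed = 102)
  expect_lt(abs(stats::cor(p2[, 1], p2[, 2], method = "kendall")), 0.03)
  p3 <- sample_pairs(copula_spec("joe", 25.38), 5000, seed = 103)
  expect_equal(stats::cor(p3[, 1], p3[, 2], method = "kendall"),
               as.numeric(kendall_tau(copula_spec("joe", 25.38))),
               tolerance = 0.02)
  # reproducibility
  expect_identical(sample_pairs(copula_spec("joe", 3), 50, seed = 9),
                   sample_pairs(copula_spec("joe", 3), 50, seed = 9))
})
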