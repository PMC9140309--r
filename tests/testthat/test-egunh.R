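test_that("EGuNH cdf endpoints and tabulated median are reproduced", {
  expect_identical(pegunh(0, 2.1, 0.1, 1.5), 0)
  expect_equal(pegunh(1e8, 2.1, 0.1, 1.5), 1)
  # the tabulated median 0.294 is a 3-dp rounding of Q(1/2) = 0.29424...;
  # the cdf is steep there, so assert the exact identity plus the printed value
  expect_equal(pegunh(qegunh(0.5, 2.1, 0.1, 1.5), 2.1, 0.1, 1.5), 0.5,
               tolerance = 1e-12)
  expect_equal(round(qegunh(0.5, 2.1, 0.1, 1.5), 3), 0.294)
  expect_equal(pegunh(0.294, 2.1, 0.1, 1.5), 0.5, tolerance = 0.02)
  expect_error(pegunh(-1, 2.1, 0.1, 1.5), "nonnegative")
})

test_that("EGuNH quantile function reproduces the tabulated quartiles", {
  tab <- rbind(c(0.275, 0.294, 0.311),   # (2.1, 0.10, 1.5)
               c(0.255, 0.310, 0.361),   # (2.1, 0.29, 1.5)
               c(0.390, 0.436, 0.482))   # (6.5, 0.33, 1.35)
  for (i in seq_along(anchor_rows)) {
    p <- anchor_rows[[i]]
    expect_equal(round(qegunh(c(0.25, 0.5, 0.75), p[1], p[2], p[3]), 3),
                 tab[i, ], info = paste(p, collapse = ","))
  }
  expect_identical(qegunh(0, 2.1, 0.29, 1.5), 0)
})

test_that("quantile round trip holds to 1e-9 wherever the quantile is representable", {
  u <- c(1e-6, 1e-3, seq(0.05, 0.95, by = 0.05), 1 - 1e-3, 1 - 1e-6)
  sets <- c(anchor_rows,
            lapply(seq_len(nrow(shape_grid)), function(r)
              c(shape_grid$theta[r], shape_grid$sigma[r], 1.5)))
  for (p in sets) {
    ok <- representable_u(u, p[1], p[2])
    q <- qegunh(u, p[1], p[2], p[3])
    err <- abs(pegunh(q[ok], p[1], p[2], p[3]) - u[ok])
    expect_lt(max(err), 1e-9)
    # below the double floor the quantile collapses to exactly 0
    expect_true(all(q[!ok] == 0))
  }
})

test_that("lambda acts as a pure scale on the quantiles", {
  u <- c(0.1, 0.5, 0.9)
  expect_equal(qegunh(u, 2.1, 0.29, 1.5, lambda = 4),
               qegunh(u, 2.1, 0.29, 1.5) / 4, tolerance = 1e-12)
})

test_that("EGuNH density normalizes, is stable in log space, matches dF/dx", {
  expect_equal(
    total_mass(function(x) degunh(x, 2.1, 0.29, 1.5),
               function(x) pegunh(x, 2.1, 0.29, 1.5),
               function(u) qegunh(u, 2.1, 0.29, 1.5)),
    1, tolerance = 1e-6)
  # log-density representable over [1e-8, 30]; beyond x ~ 35 (hundreds of
  # sds into the tail at these shapes) its true value drops below the
  # smallest double and the clamp to -Inf is the honest answer
  expect_true(all(is.finite(
    degunh(10^seq(-8, log10(30), length.out = 60), 2.1, 0.29, 1.5,
           log = TRUE))))
  x <- qegunh(c(0.2, 0.5, 0.8), 2.1, 0.1, 1.5)
  h <- x * 1e-6
  dF <- (pegunh(x + h, 2.1, 0.1, 1.5) - pegunh(x - h, 2.1, 0.1, 1.5)) / (2 * h)
  expect_equal(degunh(x, 2.1, 0.1, 1.5), dF, tolerance = 1e-6)
})

test_that("quadrature moments reproduce the tabulated values at 3 decimals", {
  tab <- rbind(c(0.292, 0.086, 0.026, 0.008),   # (2.1, 0.10, 1.5)
               c(0.306, 0.100, 0.034, 0.012),   # (2.1, 0.29, 1.5)
               c(0.436, 0.194, 0.089, 0.041))   # (6.5, 0.33, 1.35)
  for (i in seq_along(anchor_rows)) {
    p <- anchor_rows[[i]]
    m <- vapply(1:4, function(s) egunh_moment(s, p[1], p[2], p[3]), 0)
    expect_equal(round(m, 3), tab[i, ], info = paste(p, collapse = ","))
  }
})

test_that("moments agree with the quantile-space integral and variance >= 0", {
  for (s in 1:2) {
    qint <- stats::integrate(function(u) qegunh(u, 2.1, 0.29, 1.5)^s, 0, 1,
                             rel.tol = 1e-10)$value
    expect_equal(egunh_moment(s, 2.1, 0.29, 1.5), qint, tolerance = 1e-6)
  }
  set.seed(31)
  for (i in 1:10) {
    p <- exp(stats::runif(3, -0.5, 1))
    v <- egunh_moment(2, p[1], p[2], p[3]) - egunh_moment(1, p[1], p[2], p[3])^2
    expect_gte(v, 0)
  }
})

test_that("series moment route carries a convergence diagnostic", {
  m <- egunh_moment(1, 2.1, 0.29, 1.5, method = "series", M = 40, inner = 30)
  expect_true(is.finite(m))
  expect_type(attr(m, "converged"), "logical")
})

test_that("incomplete moments are monotone and reach the full moment", {
  m1 <- egunh_moment(1, 2.1, 0.29, 1.5)
  expect_equal(egunh_incomplete_moment(1, Inf, 2.1, 0.29, 1.5), m1,
               tolerance = 1e-8)
  ys <- qegunh(c(0.2, 0.5, 0.8), 2.1, 0.29, 1.5)
  inc <- vapply(ys, function(y) egunh_incomplete_moment(1, y, 2.1, 0.29, 1.5), 0)
  expect_true(all(diff(inc) > 0))
  expect_true(all(inc <= m1))
})

test_that("mean-deviation identities match direct integrals", {
  mu <- egunh_moment(1, 2.1, 0.29, 1.5)
  M <- qegunh(0.5, 2.1, 0.29, 1.5)
  d <- egunh_mean_deviations(2.1, 0.29, 1.5)
  expect_true(all(d >= 0))
  direct1 <- stats::integrate(function(x) abs(x - mu) * degunh(x, 2.1, 0.29, 1.5),
                              0, Inf, rel.tol = 1e-10)$value
  direct2 <- stats::integrate(function(x) abs(x - M) * degunh(x, 2.1, 0.29, 1.5),
                              0, Inf, rel.tol = 1e-10)$value
  expect_equal(unname(d[1]), direct1, tolerance = 1e-6)
  expect_equal(unname(d[2]), direct2, tolerance = 1e-6)
})

test_that("Lorenz and Bonferroni curves behave as inequality curves", {
  pg <- seq(0.05, 0.95, by = 0.05)
  L <- egunh_lorenz(pg, 2.1, 0.29, 1.5)
  expect_true(all(diff(L) > 0))
  expect_true(all(diff(diff(L)) >= -1e-8))          # convexity
  expect_true(all(L <= pg + 1e-10))
  expect_gt(egunh_lorenz(0.999, 2.1, 0.29, 1.5), 0.99)
  B <- egunh_bonferroni(pg, 2.1, 0.29, 1.5)
  expect_true(all(B <= 1 + 1e-10))
})

test_that("quantile shape measures reproduce tabulated values and identities", {
  tabB <- c(-0.060, -0.041, -0.003)
  tabM <- c(1.248, 1.231, 1.234)
  for (i in seq_along(anchor_rows)) {
    p <- anchor_rows[[i]]
    expect_equal(round(bowley_skewness(p[1], p[2], p[3]), 3), tabB[i])
    expect_equal(round(moors_kurtosis(p[1], p[2], p[3]), 3), tabM[i])
  }
  expect_equal(macgillivray_skewness(0.25, 2.1, 0.29, 1.5),
               bowley_skewness(2.1, 0.29, 1.5), tolerance = 1e-14)
  set.seed(77)
  for (i in 1:10) {
    p <- exp(stats::runif(3, -0.5, 1))
    expect_lte(abs(bowley_skewness(p[1], p[2], p[3])), 1)
  }
  # MacGillivray curve against direct quantile evaluation
  us <- c(0.05, 0.15, 0.35, 0.45)
  direct <- (qegunh(1 - us, 2.1, 0.29, 1.5) + qegunh(us, 2.1, 0.29, 1.5) -
               2 * qegunh(0.5, 2.1, 0.29, 1.5)) /
    (qegunh(1 - us, 2.1, 0.29, 1.5) - qegunh(us, 2.1, 0.29, 1.5))
  expect_equal(macgillivray_skewness(us, 2.1, 0.29, 1.5), direct,
               tolerance = 1e-14)
})

test_that("risk measures: VaR is the quantile and ES averages it", {
  qs <- seq(0.55, 0.95, by = 0.05)
  expect_identical(egunh_var(qs, 6.5, 0.33, 1.35), qegunh(qs, 6.5, 0.33, 1.35))
  expect_equal(round(egunh_var(0.5, 6.5, 0.33, 1.35), 3), 0.436)
  prof <- egunh_risk_profile(2.1, 0.29, 1.5, levels = qs)
  expect_true(all(diff(prof$var) > 0))
  expect_true(all(diff(prof$es) > 0))
  expect_true(all(prof$es <= prof$var))
})
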