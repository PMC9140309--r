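nh15 <- make_baseline("nh", c(alpha = 1.5, lambda = 1))

test_that("family cdf hits 0 and 1 at the support endpoints and is monotone", {
  for (r in seq_len(nrow(shape_grid))) {
    th <- shape_grid$theta[r]; si <- shape_grid$sigma[r]
    expect_identical(pegug(0, th, si, nh15), 0)
    expect_equal(pegug(Inf, th, si, nh15), 1)
    x <- qegug(seq(0.001, 0.999, length.out = 1000), th, si, nh15)
    expect_true(all(diff(pegug(x, th, si, nh15)) >= 0))
  }
})

test_that("family cdf reproduces the tabulated median over the NH baseline", {
  # Q(1/2) = 0.30977... prints as 0.310; assert the exact identity and the
  # printed rounding, plus the cdf value at the printed point
  m <- qegug(0.5, 2.1, 0.29, nh15)
  expect_equal(round(m, 3), 0.310)
  expect_equal(pegug(m, 2.1, 0.29, nh15), 0.5, tolerance = 1e-12)
  expect_equal(pegug(0.310, 2.1, 0.29, nh15), 0.5, tolerance = 0.01)
})

test_that("family pdf is a density and the derivative of the cdf", {
  for (pars in list(c(2, 0.5), c(0.7, 1.3))) {
    th <- pars[1]; si <- pars[2]
    expect_equal(
      total_mass(function(x) degug(x, th, si, nh15),
                 function(x) pegug(x, th, si, nh15),
                 function(u) qegug(u, th, si, nh15)),
      1, tolerance = 1e-6)
    x <- qegug(c(0.1, 0.3, 0.5, 0.7, 0.9), th, si, nh15)
    h <- x * 1e-6
    dF <- (pegug(x + h, th, si, nh15) - pegug(x - h, th, si, nh15)) / (2 * h)
    expect_equal(degug(x, th, si, nh15), dF, tolerance = 1e-6)
    expect_true(all(degug(x, th, si, nh15) >= 0))
  }
})

test_that("survival, hazard and cumulative hazard are mutually consistent", {
  x <- qegug(seq(0.05, 0.95, by = 0.05), 2.1, 0.29, nh15)
  Fx <- pegug(x, 2.1, 0.29, nh15)
  sf <- pegug(x, 2.1, 0.29, nh15, lower.tail = FALSE)
  expect_equal(Fx + sf, rep(1, length(x)), tolerance = 1e-14)
  expect_equal(Hegug(x, 2.1, 0.29, nh15), -log(sf), tolerance = 1e-12)
  expect_equal(hegug(x, 2.1, 0.29, nh15) * sf, degug(x, 2.1, 0.29, nh15),
               tolerance = 1e-10)
})

test_that("quantile inversion round-trips through the cdf", {
  u <- seq(0.01, 0.99, by = 0.01)
  for (r in seq_len(nrow(shape_grid))) {
    th <- shape_grid$theta[r]; si <- shape_grid$sigma[r]
    uo <- u[representable_u(u, th, si)]
    expect_lt(max(abs(pegug(qegug(uo, th, si, nh15), th, si, nh15) - uo)), 1e-9)
  }
  # tabulated median over the NH(1.35) baseline
  b135 <- make_baseline("nh", c(alpha = 1.35, lambda = 1))
  expect_equal(round(qegug(0.5, 6.5, 0.33, b135), 3), 0.436)
  # generic inversion agrees with the closed-form special model
  u2 <- c(1e-5, 0.1, 0.5, 0.9, 1 - 1e-5)
  expect_lt(max(abs(qegug(u2, 2.1, 0.29, nh15) - qegunh(u2, 2.1, 0.29, 1.5))),
            1e-10)
})

test_that("family and closed-form EGuNH functions agree over the NH baseline", {
  x <- seq(0.05, 3, length.out = 20)
  expect_lt(max(abs(pegug(x, 2.1, 0.29, nh15) - pegunh(x, 2.1, 0.29, 1.5))),
            1e-12)
  expect_lt(max(abs(degug(x, 2.1, 0.29, nh15) - degunh(x, 2.1, 0.29, 1.5))),
            1e-12)
})

test_that("theta = 1 reduces the cdf to the single-bracket form", {
  # hand-coded one-off: F = 1 - exp{-(-log Z)^{-1/sigma}}
  x <- seq(0.1, 4, length.out = 50)
  Z <- nh15$cdf(x)
  expect_equal(pegug(x, 1, 0.7, nh15), 1 - exp(-(-log(Z))^(-1 / 0.7)),
               tolerance = 1e-12)
})

test_that("sampling is reproducible, in-support, and matches the cdf", {
  s1 <- regug(50, 2, 0.5, nh15, seed = 99)
  s2 <- regug(50, 2, 0.5, nh15, seed = 99)
  expect_identical(s1, s2)
  x <- regug(1e4, 2, 0.5, nh15, seed = 7)
  expect_true(all(x >= 0 & is.finite(x)))
  ks <- stats::ks.test(x, function(q) pegug(q, 2, 0.5, nh15))
  expect_gt(ks$p.value, 0.01)
})

test_that("order-statistic density follows the exact beta form", {
  # single observation: f_{1:1} = f
  x <- c(0.2, 0.5, 1, 2)
  expect_equal(degug_order(x, 1, 1, 2, 0.5, nh15), degug(x, 2, 0.5, nh15),
               tolerance = 1e-14)
  # normalization for an interior rank
  f25 <- function(x) degug_order(x, 2, 5, 2, 0.5, nh15)
  expect_equal(total_mass(f25, function(x) stats::pbeta(
    pegug(x, 2, 0.5, nh15), 2, 4), function(u) qegug(u, 2, 0.5, nh15)),
    1, tolerance = 1e-5)
  # sample maxima follow n f F^{n-1}
  maxima <- vapply(1:2000, function(i) {
    max(regug(5, 2, 0.5, nh15, seed = 40000 + i))
  }, 0)
  ks <- stats::ks.test(maxima, function(q) pegug(q, 2, 0.5, nh15)^5)
  expect_gt(ks$p.value, 0.01)
  expect_error(degug_order(1, 6, 5, 2, 0.5, nh15), "rank")
})

test_that("shape diagnosis classifies density and hazard patterns", {
  # spike-at-zero parameter set: reversed-J density, no interior critical point
  s <- egug_shape(0.91, 2.1, nh15)
  expect_identical(s$pdf_class, "monotone-decreasing")
  expect_length(s$pdf_critical, 0)
  # sharply peaked set: exactly one interior maximum, increasing hazard
  s2 <- egug_shape(2.1, 0.1, nh15)
  expect_identical(s2$pdf_class, "unimodal")
  expect_length(s2$pdf_critical, 1)
  expect_identical(s2$hrf_class, "increasing")
  # hazard classification stable under grid doubling
  s2b <- egug_shape(2.1, 0.1, nh15, grid_n = 800)
  expect_identical(s2$hrf_class, s2b$hrf_class)
})
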