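# Shared fixtures: parameter grids and a central-difference gradient.

# shape grid spanning light to heavy tails
shape_grid <- expand.grid(theta = c(0.3, 1, 3), sigma = c(0.3, 1, 3))

# Table-style anchor parameter sets (theta, sigma, alpha), lambda = 1
anchor_rows <- list(c(2.1, 0.1, 1.5), c(2.1, 0.29, 1.5), c(6.5, 0.33, 1.35))

num_grad <- function(f, p, rel_h = 1e-6) {
  vapply(seq_along(p), function(i) {
    h <- max(abs(p[i]), 1e-3) * rel_h
    up <- p; up[i] <- p[i] + h
    dn <- p; dn[i] <- p[i] - h
    (f(up) - f(dn)) / (2 * h)
  }, 0)
}

# total probability: integral of the density from the smallest
# representable quantile upward, plus the cdf mass below it. The bulk is
# integrated in log-x (the left tail can spike across many decades); the
# far tail in x-space, where the density decays double-exponentially.
total_mass <- function(pdf, cdf, qf) {
  lo <- 0
  for (eps in c(1e-8, 1e-6, 1e-4, 1e-2, 0.05, 0.1)) {
    lo <- qf(eps)
    if (lo > 1e-250) break
  }
  med <- qf(0.5); hi <- qf(1 - 1e-6)
  fy <- function(y) pdf(exp(y)) * exp(y)
  stats::integrate(fy, log(lo), log(med), rel.tol = 1e-9,
                   subdivisions = 500L)$value +
    stats::integrate(fy, log(med), log(hi), rel.tol = 1e-9,
                     subdivisions = 500L)$value +
    stats::integrate(pdf, hi, Inf, rel.tol = 1e-9)$value +
    cdf(lo)
}

# u-values of the probability grid whose exact quantile is representable
# in double precision: the inner -log Z value must stay below ~700 or the
# quantile underflows (mass compressed below 1e-308)
representable_u <- function(u, theta, sigma) {
  a <- -log(u) / theta
  logA <- ifelse(a > 30, -a, log(-log(-expm1(-a))))
  exp(-sigma * logA) < 700
}

test_baselines <- list(
  exponential = c(alpha = 0.7),
  weibull = c(a = 1, b = 2),
  burr12 = c(a = 2, b = 3),
  nh = c(alpha = 1.5, lambda = 1),
  rayleigh = c(a = 0.5))
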