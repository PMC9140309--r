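## The exponentiated Gumbel-G transform.
##
## For a baseline cdf Z(x) the family cdf is
##   F(x) = [1 - exp{-(-log Z(x))^{-1/sigma}}]^theta,  theta, sigma > 0.
## All arithmetic is carried out in log space: with L = -log Z(x) and
## A = L^{-1/sigma} = exp(-log(L)/sigma),
##   log F = theta * log(1 - e^{-A}),
##   log f = log(theta) - log(sigma) + log z(x) + L - (1/sigma + 1) log L
##           - A + (theta - 1) log(1 - e^{-A}).

check_family <- function(theta, sigma, baseline) {
  check_positive(theta, "theta")
  check_positive(sigma, "sigma")
  if (!inherits(baseline, "egug_baseline"))
    stop("'baseline' must be created with make_baseline()", call. = FALSE)
  invisible(NULL)
}

## A = (-log Z(x))^{-1/sigma}, elementwise; Inf at the upper support end.
.family_A <- function(x, sigma, baseline) {
  logL <- baseline$log_neg_log_cdf(x)
  exp(-logL / sigma)
}

#' Exponentiated Gumbel-G family distribution functions
#'
#' Distribution function, density, quantile function, random generation,
#' hazard and cumulative hazard for the exponentiated Gumbel-G (EGuG)
#' family over an arbitrary registered baseline. With baseline cdf
#' \eqn{Z(x;\varphi)}, the family cdf is
#' \deqn{F(x) = \left[1 - \exp\{-(-\log Z(x))^{-1/\sigma}\}\right]^\theta,}
#' with shape parameters \eqn{\theta > 0} and \eqn{\sigma > 0}. Sampling
#' is by quantile inversion, so draws are reproducible for a fixed seed.
#'
#' @param x Vector of quantiles.
#' @param u Vector of probabilities.
#' @param n Number of draws.
#' @param theta,sigma Family shape parameters, both strictly positive.
#' @param baseline An `egug_baseline` from [make_baseline()].
#' @param lower.tail If `FALSE`, return the survival function.
#' @param log.p,log If `TRUE`, return log probabilities / log density.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return `pegug` the cdf (or sf), `degug` the density, `qegug` the
#'   quantile function, `regug` a vector of draws, `hegug` the hazard
#'   rate, `Hegug` the cumulative hazard.
#' @examples
#' b <- make_baseline("weibull", c(a = 1, b = 2))
#' pegug(1, theta = 2, sigma = 0.5, baseline = b)
#' qegug(0.5, theta = 2, sigma = 0.5, baseline = b)
#' @name egug-family
NULL

#' @rdname egug-family
#' @export
pegug <- function(x, theta, sigma, baseline, lower.tail = TRUE, log.p = FALSE) {
  check_family(theta, sigma, baseline)
  A <- .family_A(x, sigma, baseline)
  logF <- theta * log1mexp(A)
  if (lower.tail) {
    if (log.p) logF else exp(logF)
  } else {
    sf <- -expm1(logF)
    if (log.p) log(sf) else sf
  }
}

#' @rdname egug-family
#' @export
degug <- function(x, theta, sigma, baseline, log = FALSE) {
  check_family(theta, sigma, baseline)
  logL <- baseline$log_neg_log_cdf(x)
  L <- exp(logL)
  A <- exp(-logL / sigma)
  logf <- log(theta) - log(sigma) + baseline$logpdf(x) + L -
    (1 / sigma + 1) * logL - A + (theta - 1) * log1mexp(A)
  logf[x <= baseline$support[1] | x >= baseline$support[2]] <- -Inf
  logf[!is.finite(logf)] <- -Inf
  if (log) logf else exp(logf)
}

#' @rdname egug-family
#' @export
qegug <- function(u, theta, sigma, baseline) {
  check_family(theta, sigma, baseline)
  check_prob(u, closed_left = TRUE)
  out <- numeric(length(u))
  pos <- u > 0
  a <- -log(u[pos]) / theta            # u^{1/theta} = e^{-a}
  logA <- ifelse(a > 30, -a, log(-log1mexp(a)))  # A = -log(1 - u^{1/theta})
  L <- exp(-sigma * logA)              # -log Z at the quantile
  out[pos] <- baseline$quantile_nl(L)
  out
}

#' @rdname egug-family
#' @export
regug <- function(n, theta, sigma, baseline, seed = NULL) {
  check_family(theta, sigma, baseline)
  with_seed(seed, qegug(stats::runif(n), theta, sigma, baseline))
}

#' @rdname egug-family
#' @export
hegug <- function(x, theta, sigma, baseline) {
  sf <- pegug(x, theta, sigma, baseline, lower.tail = FALSE)
  if (any(sf == 0 & x < baseline$support[2]))
    stop("survival function underflows to 0; hazard rate undefined",
         call. = FALSE)
  degug(x, theta, sigma, baseline) / sf
}

#' @rdname egug-family
#' @export
Hegug <- function(x, theta, sigma, baseline) {
  -pegug(x, theta, sigma, baseline, lower.tail = FALSE, log.p = TRUE)
}

#' Density of an order statistic from an EGuG sample
#'
#' Density of the `i`-th order statistic of an i.i.d. sample of size `n`,
#' computed from the exact beta form
#' \eqn{f_{i:n}(x) = f(x)F(x)^{i-1}(1-F(x))^{n-i} / B(i, n-i+1)}.
#'
#' @inheritParams egug-family
#' @param i Rank, `1 <= i <= n`.
#' @param n Sample size.
#' @return Density values of the order statistic.
#' @export
degug_order <- function(x, i, n, theta, sigma, baseline) {
  if (i < 1 || i > n || i != round(i) || n != round(n))
    stop("rank 'i' must be an integer in 1..n", call. = FALSE)
  Fx <- pegug(x, theta, sigma, baseline)
  stats::dbeta(Fx, i, n - i + 1) * degug(x, theta, sigma, baseline)
}

## numeric derivative of f on a relative central-difference stencil
.num_deriv <- function(f, x, h = NULL) {
  if (is.null(h)) h <- pmax(abs(x), 1e-4) * 1e-6
  (f(x + h) - f(x - h)) / (2 * h)
}

## sign-change refinement: bisect the numeric derivative between grid points
.refine_roots <- function(dfun, grid) {
  s <- sign(dfun(grid))
  idx <- which(s[-1] * s[-length(s)] < 0)
  roots <- vapply(idx, function(j)
    stats::uniroot(dfun, c(grid[j], grid[j + 1]), tol = 1e-10)$root, 0)
  # merge near-duplicates
  if (length(roots) > 1) {
    roots <- sort(roots)
    roots <- roots[c(TRUE, diff(roots) > 1e-6)]
  }
  roots
}

#' Numeric shape diagnosis of the EGuG density and hazard
#'
#' Locates interior critical points of the log-density and of the hazard
#' rate on a log-spaced grid (refined by bisection of the numeric
#' derivative) and classifies the shapes: the density as
#' monotone-decreasing, unimodal or other; the hazard as increasing,
#' decreasing, bathtub, upside-down-bathtub or other. Critical points
#' closer than `1e-6` are merged; ambiguous patterns yield `"other"`.
#'
#' @inheritParams egug-family
#' @param grid_n Number of grid points (default 400).
#' @param p_lim Tail probabilities delimiting the scanned interval.
#' @return A list with `pdf_class`, `pdf_critical`, `hrf_class`,
#'   `hrf_critical`.
#' @export
egug_shape <- function(theta, sigma, baseline, grid_n = 400,
                       p_lim = c(1e-4, 1 - 1e-4)) {
  check_family(theta, sigma, baseline)
  lo <- qegug(p_lim[1], theta, sigma, baseline)
  hi <- qegug(p_lim[2], theta, sigma, baseline)
  lo <- max(lo, hi * 1e-10)   # lower tail can underflow to 0 (spike at 0)
  grid <- exp(seq(log(lo), log(hi), length.out = grid_n))

  dlpdf <- function(x) .num_deriv(function(z) degug(z, theta, sigma, baseline,
                                                    log = TRUE), x)
  pdf_cr <- .refine_roots(dlpdf, grid)
  s_pdf <- sign(dlpdf(grid))
  pdf_class <- if (length(pdf_cr) == 0 && all(s_pdf <= 0)) "monotone-decreasing"
  else if (length(pdf_cr) == 1 && s_pdf[1] > 0 && s_pdf[length(s_pdf)] < 0) "unimodal"
  else "other"

  dh <- function(x) .num_deriv(function(z) hegug(z, theta, sigma, baseline), x)
  hrf_cr <- .refine_roots(dh, grid)
  s_h <- sign(dh(grid))
  hrf_class <-
    if (length(hrf_cr) == 0 && all(s_h >= 0)) "increasing"
    else if (length(hrf_cr) == 0 && all(s_h <= 0)) "decreasing"
    else if (length(hrf_cr) == 1 && s_h[1] < 0) "bathtub"
    else if (length(hrf_cr) == 1 && s_h[1] > 0) "upside-down-bathtub"
    else "other"

  list(pdf_class = pdf_class, pdf_critical = pdf_cr,
       hrf_class = hrf_class, hrf_critical = hrf_cr)
}
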