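## Formal exp-G series representation of the family cdf (experimental).
##
## The family cdf admits a formal expansion F(x) = sum_m Pi_m Z(x)^m in
## exponentiated-baseline ("exp-G") terms. The coefficient series rests on
## a Stirling-polynomial expansion of [-log(1-z)]^c whose printed source
## is ambiguous (only orders 0..2 of P_k are available and one index is
## unbound), so the whole path is flagged experimental: coefficients are
## returned together with a convergence diagnostic, and every downstream
## quantity in this package is computed by quadrature or closed form
## instead. This module exists for fidelity of the representation, not as
## a computational route.

#' Stirling polynomials of low order
#'
#' The polynomials \eqn{P_k(c)} appearing in the series expansion of
#' \eqn{[-\log(1-z)]^c}: \eqn{P_0 = 1/2}, \eqn{P_1(c) = c(3c+5)/24},
#' \eqn{P_2(c) = c(c^2+5c+6)/48}. Only orders 0--2 are supported; higher
#' orders are not defined in this implementation and raise an error.
#'
#' @param k Order, one of 0, 1, 2.
#' @param c Argument (any real).
#' @return Value of \eqn{P_k(c)}.
#' @export
stirling_polynomial <- function(k, c) {
  if (length(k) != 1L || !k %in% 0:2)
    stop("only Stirling polynomial orders k = 0, 1, 2 are supported",
         call. = FALSE)
  switch(as.character(k),
         "0" = rep_len(0.5, length(c)),
         "1" = c * (3 * c + 5) / 24,
         "2" = c * (c^2 + 5 * c + 6) / 48)
}

#' Exp-G expansion coefficients of the family cdf (experimental)
#'
#' Computes truncated coefficients \eqn{\Pi_m} of the formal series
#' \eqn{F(x) = \sum_m \Pi_m Z(x)^m}. The inner double sum over
#' \eqn{(i, j)} is truncated at `inner`, the Stirling-polynomial sum uses
#' orders 0--2, and the gamma ratio
#' \eqn{\Gamma(m - c)/\Gamma(-c)} is evaluated as a rising factorial to
#' avoid gamma poles. A tail-magnitude diagnostic sets `converged = FALSE`
#' when the last decade of partial coefficient magnitudes still moves by
#' more than `tol`; non-convergence is reported, never raised.
#'
#' @inheritParams egug-family
#' @param M Truncation order of the outer series, `M >= 1`.
#' @param inner Truncation of the inner i/j sums (default 40).
#' @param tol Tail-movement tolerance for the convergence flag.
#' @return A list with `order` (= `M`), `pi_m` (length-`M` coefficient
#'   vector), `tail` (largest coefficient magnitude in the last decade)
#'   and `converged` (logical diagnostic).
#' @export
egug_expansion <- function(theta, sigma, M, inner = 40, tol = 1e-6) {
  check_positive(theta, "theta")
  check_positive(sigma, "sigma")
  if (M < 1 || M != round(M)) stop("'M' must be a positive integer", call. = FALSE)

  i <- seq_len(inner)
  j <- seq_len(inner)
  # (i,j)-independent pieces
  lfac_i <- lgamma(i + 1)
  lchoose_tj <- lchoose(theta, j)
  pi_m <- numeric(M)
  for (m in seq_len(M)) {
    acc <- 0
    for (k in 0:2) {
      cvec <- -i * (k + 1) / sigma          # argument of the rising factorial
      Pk <- stirling_polynomial(k, -i / sigma)
      # Gamma(m + cvec)/Gamma(cvec) = prod_{t=0}^{m-1} (cvec + t)
      poch <- vapply(cvec, function(cc) prod(cc + 0:(m - 1)), 0)
      for (jj in j) {
        term_i <- (-1)^(i + jj) * exp(i * log(jj) - lfac_i + lchoose_tj[jj]) *
          poch * Pk / m
        acc <- acc + sum(term_i)
      }
    }
    pi_m[m] <- (-1)^(m + 1) * acc
  }
  last <- max(1L, M - max(1L, M %/% 10L) + 1L)
  tail_mag <- max(abs(pi_m[last:M]))
  list(order = M, pi_m = pi_m, tail = tail_mag,
       converged = is.finite(tail_mag) && tail_mag < tol)
}

#' Partial series reconstruction of the family cdf (experimental)
#'
#' Evaluates \eqn{\sum_m \Pi_m Z(x)^m} from [egug_expansion()]
#' coefficients, for comparison against [pegug()]. Only meaningful when
#' the expansion's convergence diagnostic is `TRUE`.
#'
#' @inheritParams egug-family
#' @param coef Result of [egug_expansion()].
#' @return Approximate cdf values.
#' @export
egug_expansion_cdf <- function(x, coef, baseline) {
  Z <- baseline$cdf(x)
  vapply(Z, function(z) sum(coef$pi_m * z^seq_len(coef$order)), 0)
}
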