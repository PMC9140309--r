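## Model-adequacy statistics and diagnostic transforms.
##
## A* and W* are the Chen-Balakrishnan small-sample modified
## Anderson-Darling and Cramér-von Mises statistics computed from the
## probability-integral transforms of the fitted cdf; the fitted-parameter
## effect on their null distributions is ignored (the usual practice for
## this style of model ranking, documented as a caveat). The KS statistic
## is the both-sided sup against the empirical step function with the
## asymptotic Kolmogorov p-value.

#' Anderson-Darling and Cramér-von Mises adequacy statistics
#'
#' Computes \eqn{A^2} and \eqn{W^2} from the sorted probability-integral
#' transforms \eqn{u_i = F(x_{(i)})} of the fitted cdf, then applies the
#' small-sample modifications
#' \eqn{A^* = A^2(1 + 0.75/n + 2.25/n^2)} and
#' \eqn{W^* = W^2(1 + 0.5/n)}.
#'
#' @param x Data vector, `n >= 2`.
#' @param cdf Function of one argument: the fitted cdf under test.
#' @return Named vector `c(a_star, w_star)`.
#' @export
ad_cvm <- function(x, cdf) {
  n <- length(x)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  u <- sort(cdf(sort(x)))
  if (any(u <= 0 | u >= 1))
    stop("fitted cdf values must lie strictly inside (0,1)", call. = FALSE)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (log(u) + log1p(-rev(u))))
  W2 <- sum((u - (2 * i - 1) / (2 * n))^2) + 1 / (12 * n)
  c(a_star = A2 * (1 + 0.75 / n + 2.25 / n^2),
    w_star = W2 * (1 + 0.5 / n))
}

#' One-sample Kolmogorov-Smirnov statistic and asymptotic p-value
#'
#' The sup of both one-sided discrepancies between the fitted cdf and the
#' empirical step function, with the asymptotic Kolmogorov-distribution
#' p-value \eqn{2\sum_{k\ge1} (-1)^{k-1} e^{-2 k^2 n D^2}} (100-term
#' truncation, clamped to (0, 1]).
#'
#' @inheritParams ad_cvm
#' @return Named vector `c(d_star, p_value)`.
#' @export
ks_stat <- function(x, cdf) {
  n <- length(x)
  u <- cdf(sort(x))
  i <- seq_len(n)
  D <- max(i / n - u, u - (i - 1) / n)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * n * D^2))
  c(d_star = D, p_value = min(max(p, 0), 1))
}

#' Scaled total-time-on-test (TTT) transform
#'
#' Points \eqn{(i/n, T_i)} with
#' \eqn{T_i = [\sum_{j \le i} x_{(j)} + (n-i) x_{(i)}] / \sum_j x_{(j)}}.
#' The curve starts at (0, 0), ends at (1, 1) and is nondecreasing; its
#' concavity pattern diagnoses increasing, decreasing or bathtub hazards.
#'
#' @param x Nonnegative data vector, `n >= 2`, not all zero.
#' @return A `data.frame` with columns `p` (= i/n, including 0) and `ttt`.
#' @export
ttt_transform <- function(x) {
  if (length(x) < 2 || any(x < 0)) stop("need n >= 2 nonnegative values",
                                        call. = FALSE)
  if (sum(x) == 0) stop("all-zero data", call. = FALSE)
  xs <- sort(x)
  n <- length(xs)
  Ti <- (cumsum(xs) + (n - seq_len(n)) * xs) / sum(xs)
  data.frame(p = c(0, seq_len(n) / n), ttt = c(0, Ti))
}

#' Information criteria of a fit
#'
#' `AIC = 2k + 2(-loglik)` and `BIC = k log(n) + 2(-loglik)` with `k` the
#' number of free parameters.
#'
#' @param fit An [egug_fit()] result.
#' @param n Sample size (defaults to the fit's).
#' @return Named vector `c(aic, bic)`.
#' @export
information_criteria <- function(fit, n = fit$n) {
  k <- length(fit$params_hat)
  c(aic = 2 * k - 2 * fit$loglik, bic = k * log(n) - 2 * fit$loglik)
}

#' Fit and rank several candidate models on one dataset
#'
#' Fits each model by [egug_fit()], computes \eqn{-\hat\ell}, AIC, BIC,
#' \eqn{A^*}, \eqn{W^*}, the KS statistic and its p-value, and ranks the
#' models by AIC. A model whose fit fails is reported as an `NA` row
#' without aborting the others.
#'
#' @param x Data vector of strictly positive observations.
#' @param models Character vector of model names accepted by [egug_fit()].
#' @param starts,seed Passed to [egug_fit()].
#' @return A `data.frame` of class `gof_report` with one row per model:
#'   `model`, `neg_loglik`, `aic`, `bic`, `a_star`, `w_star`, `d_star`,
#'   `p_value`, `rank_aic`, sorted by AIC.
#' @examples
#' x <- regunh(100, 2.2, 0.45, 0.5, seed = 3)
#' compare_models(x, c("egunh", "nh"), starts = 4)
#' @export
compare_models <- function(x, models = c("egunh", "nh", "exponential"),
                           starts = 8, seed = 1) {
  rows <- lapply(models, function(m) {
    fit <- tryCatch(egug_fit(x, m, starts = starts, seed = seed),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(model = m, neg_loglik = NA_real_, aic = NA_real_,
                        bic = NA_real_, a_star = NA_real_, w_star = NA_real_,
                        d_star = NA_real_, p_value = NA_real_))
    ic <- information_criteria(fit)
    def <- .fit_model(m, fit$baseline, fit$fix_lambda)
    cdf <- function(z) def$cdf(z, fit$params_hat)
    aw <- ad_cvm(x, cdf)
    ks <- ks_stat(x, cdf)
    data.frame(model = m, neg_loglik = -fit$loglik, aic = ic[["aic"]],
               bic = ic[["bic"]], a_star = aw[["a_star"]],
               w_star = aw[["w_star"]], d_star = ks[["d_star"]],
               p_value = ks[["p_value"]])
  })
  rep_df <- do.call(rbind, rows)
  rep_df$rank_aic <- rank(rep_df$aic, na.last = "keep")
  rep_df <- rep_df[order(rep_df$aic), ]
  rownames(rep_df) <- NULL
  class(rep_df) <- c("gof_report", "data.frame")
  rep_df
}
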