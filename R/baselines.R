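## Baseline registry.
##
## Every registered baseline has support (0, upper) and a cdf of the form
## Z(x) = 1 - exp(-g(x)), where g is the baseline's cumulative hazard.
## Each registry row supplies g, its derivative and its inverse; the cdf,
## pdf, quantile and the stable -log Z(x) used by the family transform are
## derived from g so that all tail arithmetic goes through log1p/expm1.

.baseline_registry <- list(
  exponential = list(
    params = "alpha",
    cumhaz = function(x, phi) phi[["alpha"]] * x,
    cumhaz_deriv = function(x, phi) rep_len(phi[["alpha"]], length(x)),
    cumhaz_inv = function(y, phi) y / phi[["alpha"]]
  ),
  weibull = list(
    params = c("a", "b"),
    cumhaz = function(x, phi) phi[["a"]] * x^phi[["b"]],
    cumhaz_deriv = function(x, phi) phi[["a"]] * phi[["b"]] * x^(phi[["b"]] - 1),
    cumhaz_inv = function(y, phi) (y / phi[["a"]])^(1 / phi[["b"]])
  ),
  burr12 = list(
    params = c("a", "b"),
    cumhaz = function(x, phi) phi[["b"]] * log1p(x^phi[["a"]]),
    cumhaz_deriv = function(x, phi)
      phi[["b"]] * phi[["a"]] * x^(phi[["a"]] - 1) / (1 + x^phi[["a"]]),
    cumhaz_inv = function(y, phi) expm1(y / phi[["b"]])^(1 / phi[["a"]])
  ),
  nh = list(
    params = c("alpha", "lambda"),
    cumhaz = function(x, phi)
      expm1(phi[["alpha"]] * log1p(phi[["lambda"]] * x)),
    cumhaz_deriv = function(x, phi)
      phi[["alpha"]] * phi[["lambda"]] *
        (1 + phi[["lambda"]] * x)^(phi[["alpha"]] - 1),
    cumhaz_inv = function(y, phi)
      expm1(log1p(y) / phi[["alpha"]]) / phi[["lambda"]]
  ),
  rayleigh = list(
    params = "a",
    cumhaz = function(x, phi) phi[["a"]] * x^2,
    cumhaz_deriv = function(x, phi) 2 * phi[["a"]] * x,
    cumhaz_inv = function(y, phi) sqrt(y / phi[["a"]])
  )
)

#' Registered baseline distributions
#'
#' @return Character vector of baseline names accepted by [make_baseline()].
#' @export
baseline_names <- function() names(.baseline_registry)

#' Construct a baseline distribution specification
#'
#' Builds the baseline object consumed by the family functions
#' ([pegug()], [degug()], ...). Each baseline is a positive lifetime
#' distribution specified through its cumulative hazard, from which the
#' cdf \eqn{Z(x)}, pdf \eqn{z(x)}, quantile function and a numerically
#' stable \eqn{-\log Z(x)} are derived.
#'
#' Registered baselines and their parameters (all strictly positive):
#' \describe{
#'   \item{`exponential`}{`alpha` (rate); \eqn{Z = 1 - e^{-\alpha x}}.}
#'   \item{`weibull`}{`a`, `b`; \eqn{Z = 1 - e^{-a x^b}}.}
#'   \item{`burr12`}{`a`, `b`; \eqn{Z = 1 - (1 + x^a)^{-b}}.}
#'   \item{`nh`}{`alpha`, `lambda` (Nadarajah-Haghighi);
#'     \eqn{Z = 1 - e^{1 - (1+\lambda x)^\alpha}}.}
#'   \item{`rayleigh`}{`a`; \eqn{Z = 1 - e^{-a x^2}}.}
#' }
#'
#' @param name Baseline name, one of [baseline_names()].
#' @param phi Named list or numeric vector of baseline parameters.
#' @return An object of class `egug_baseline`: a list with fields `name`,
#'   `phi`, `support`, and functions `cdf(x)`, `pdf(x)`, `logpdf(x)`,
#'   `quantile(u)`, `neg_log_cdf(x)` (\eqn{-\log Z}), `log_neg_log_cdf(x)`
#'   (stable \eqn{\log(-\log Z)}), and `quantile_nl(L)` (the point whose
#'   \eqn{-\log Z} equals `L`).
#' @examples
#' b <- make_baseline("nh", c(alpha = 1.5, lambda = 1))
#' b$cdf(1)
#' @export
make_baseline <- function(name, phi) {
  if (length(name) != 1L || !name %in% baseline_names())
    stop("unknown baseline '", name, "'; registered: ",
         paste(baseline_names(), collapse = ", "), call. = FALSE)
  row <- .baseline_registry[[name]]
  phi <- as.list(phi)
  if (is.null(names(phi)) || any(names(phi) == ""))
    names(phi) <- row$params[seq_along(phi)]
  missing <- setdiff(row$params, names(phi))
  if (length(missing))
    stop("baseline '", name, "' requires parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  phi <- phi[row$params]
  for (nm in row$params) check_positive(phi[[nm]], nm)

  g  <- function(x) row$cumhaz(x, phi)
  gd <- function(x) row$cumhaz_deriv(x, phi)
  gi <- function(y) row$cumhaz_inv(y, phi)

  spec <- list(
    name = name,
    phi = phi,
    support = c(0, Inf),
    cumhaz = g,
    cdf = function(x) {
      p <- numeric(length(x))
      pos <- x > 0
      p[pos] <- -expm1(-g(x[pos]))
      p
    },
    pdf = function(x) {
      d <- numeric(length(x))
      pos <- x > 0
      d[pos] <- gd(x[pos]) * exp(-g(x[pos]))
      d
    },
    logpdf = function(x) {
      d <- rep_len(-Inf, length(x))
      pos <- x > 0
      d[pos] <- log(gd(x[pos])) - g(x[pos])
      d
    },
    quantile = function(u) {
      check_prob(u, closed_left = TRUE)
      gi(-log1p(-u))
    },
    neg_log_cdf = function(x) {
      out <- rep_len(Inf, length(x))
      pos <- x > 0
      out[pos] <- -log1mexp(g(x[pos]))
      out
    },
    log_neg_log_cdf = function(x) {
      # log(-log Z); for large g, -log Z ~ e^{-g} so log(-log Z) ~ -g
      out <- rep_len(Inf, length(x))
      pos <- x > 0
      gx <- g(x[pos])
      v <- numeric(length(gx))
      big <- gx > 30
      v[big] <- -gx[big]
      v[!big] <- log(-log1mexp(gx[!big]))
      out[pos] <- v
      out
    },
    quantile_nl = function(L) gi(-log1mexp(L))
  )
  class(spec) <- "egug_baseline"
  spec
}

#' @export
print.egug_baseline <- function(x, ...) {
  cat("EGuG baseline:", x$name, "\n  parameters:",
      paste(names(x$phi), unlist(x$phi), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
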