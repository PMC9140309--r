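#' @keywords internal
"_PACKAGE"

## log(1 - exp(-a)) for a > 0 without cancellation (Maechler's identity).
log1mexp <- function(a) {
  out <- a
  big <- a > log(2)
  out[big] <- log1p(-exp(-a[big]))
  out[!big] <- log(-expm1(-a[!big]))
  out[a == Inf] <- 0
  out
}

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop("parameter '", name, "' must be a single finite value > 0", call. = FALSE)
  invisible(x)
}

check_prob <- function(u, name = "u", closed_left = FALSE) {
  lo_ok <- if (closed_left) u >= 0 else u > 0
  if (any(!is.finite(u) | !lo_ok | u >= 1))
    stop("'", name, "' must lie in ", if (closed_left) "[0,1)" else "(0,1)",
         call. = FALSE)
  invisible(u)
}
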