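# Internal helpers: truncated-normal transforms and argument checking.
#
# The truncated normal is the building block of the cohort generator: every
# biomarker is drawn from a group-conditional normal restricted to physical
# bounds. Sampling goes through the inverse CDF so that quantile-level
# (copula) coupling is exact.

#' @noRd
abort_field <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "hepafunc_spec_error")
}

#' @noRd
check_number <- function(x, field, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort_field(field, "must not be NULL")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_field(field, "must be a single finite number")
  }
  if (x < lower || x > upper) {
    abort_field(field, sprintf("must be in [%s, %s]", lower, upper))
  }
  invisible(x)
}

# CDF / quantile / sampler of N(mean, sd) truncated to [lo, hi].
# sd = 0 degenerates to a point mass at the (clamped) mean.

#' @noRd
ptnorm <- function(q, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(as.numeric(q >= mean))
  a <- pnorm((lo - mean) / sd)
  b <- pnorm((hi - mean) / sd)
  p <- (pnorm((q - mean) / sd) - a) / (b - a)
  pmin(pmax(p, 0), 1)
}

#' @noRd
qtnorm <- function(p, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), length(p)))
  a <- pnorm((lo - mean) / sd)
  b <- pnorm((hi - mean) / sd)
  mean + sd * qnorm(a + p * (b - a))
}

#' @noRd
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  qtnorm(runif(n), mean, sd, lo, hi)
}

# Gauss-Legendre nodes/weights on [a, b], cached per order.
#' @noRd
gl_rule <- local({
  cache <- list()
  function(n, a, b) {
    key <- sprintf("%d", n)
    if (is.null(cache[[key]])) cache[[key]] <<- pracma::gaussLegendre(n, -1, 1)
    r <- cache[[key]]
    list(x = (a + b) / 2 + (b - a) / 2 * r$x, w = (b - a) / 2 * r$w)
  }
})
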