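# Internal helpers: condition classes, rounding, numerics.

# All user-facing failures are classed conditions so callers (and tests)
# can dispatch on the kind of failure, not on message text.
pk_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "pkassay_error"), call = call))
}

assert_that <- function(ok, msg, class = "pkassay_config_error") {
  if (!isTRUE(ok)) pk_stop(msg, class, call = sys.call(-1))
  invisible(TRUE)
}

#' Round half away from zero
#'
#' Reporting convention for assay tables: ties round up in magnitude
#' (117.5 -> 118), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Trapezoidal integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-n] + y[-1]) / 2)
}

# Multiplicative lognormal noise, median-preserving: the noise-free value
# is the median of the noisy distribution; its mean is value*exp(sigma^2/2).
lognormal_cv_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = 0, sd = sigma))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
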