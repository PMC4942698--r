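#' Logistic sigmoid
#'
#' @param x Numeric vector or matrix.
#' @return `1 / (1 + exp(-x))`, same shape as `x`.
#' @keywords internal
sigmoid <- function(x) stats::plogis(x)

# Stop unless `cond` is a single TRUE; `...` is passed to sprintf.
.assert <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}

# Draw n sub-seeds (< 2^31) from the current RNG stream, for staged pipelines.
.spawn_seeds <- function(n) sample.int(.Machine$integer.max, n)

# Softmax with log-sum-exp guard; beta = 0 gives the uniform distribution and
# beta = Inf puts all mass on the argmax (ties split uniformly).
.softmax <- function(values, beta) {
  if (!is.finite(beta)) {
    if (beta < 0) values <- -values
    p <- as.numeric(values == max(values))
    return(p / sum(p))
  }
  z <- beta * values
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
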