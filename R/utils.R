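# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial rounding used for all displayed integers (replicate means,
#' percent yield increases). `base::round()` rounds half to even, which would
#' turn 0.5 into 0; reported integers here follow the half-away-from-zero
#' convention instead.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep (default 0).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' roundHalfUp(c(0.5, 1.5, -0.5, 2.25), 0)
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @importFrom stats median prcomp rlnorm rnorm rpois runif sd setNames t.test lm coef
#' @importFrom utils read.delim write.table
NULL

# lognormal multiplier with mean 1 and coefficient of variation cv
.lnormFactor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# random DNA strings (uppercase ACGT), vectorised over lengths
.randomDNA <- function(lengths) {
  vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

.assertScalarNumber <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
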