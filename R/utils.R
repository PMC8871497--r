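#' @importFrom stats pnorm qnorm rnorm sd var optimize coef lm predict
#' @importFrom rlang .data
NULL

# stop() with call. = FALSE and sprintf-style formatting
abort_fkmr <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) abort_fkmr(fmt, ...)
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)

# trapezoid quadrature weights on a (possibly irregular) sorted grid
trapezoid_weights <- function(grid) {
  m <- length(grid)
  assert_that(m >= 2L, "grid must contain at least two points")
  d <- diff(grid)
  w <- numeric(m)
  w[1L] <- d[1L] / 2
  w[m] <- d[m - 1L] / 2
  if (m > 2L) w[2:(m - 1L)] <- (d[-(m - 1L)] + d[-1L]) / 2
  w
}
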