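#' @keywords internal
"_PACKAGE"

## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (strict_lower && x <= lower) stopf("'%s' must be > %g", name, lower)
  if (!strict_lower && x < lower) stopf("'%s' must be >= %g", name, lower)
  if (strict_upper && x >= upper) stopf("'%s' must be < %g", name, upper)
  if (!strict_upper && x > upper) stopf("'%s' must be <= %g", name, upper)
  x
}

## trapezoidal integral and cumulative integral
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1L] - x[-n]) * (y[-1L] + y[-n]) / 2))
}

## sliding minimum over windows of k consecutive samples
sliding_min <- function(x, k) {
  n <- length(x)
  if (k > n) stopf("window of %d samples exceeds trace length %d", k, n)
  out <- x[seq_len(n - k + 1L)]
  if (k > 1L) for (j in seq_len(k - 1L)) {
    out <- pmin(out, x[seq_len(n - k + 1L) + j])
  }
  out
}

## standard gravity used throughout (m/s^2); 1 g for injury criteria
GRAV <- 9.81
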