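#' Clamped cubic interpolating spline with analytic derivatives
#'
#' Builds a C2 cubic spline through `(x, y)` knots. Endpoint first
#' derivatives may be clamped (the limb planner needs zero foot velocity at
#' lift-off and touchdown); unspecified ends get natural (zero second
#' derivative) conditions. Unlike [stats::splinefun()], the returned object
#' evaluates the analytic first and second derivative of the same
#' polynomial, which the joint planner uses for angular velocities and
#' accelerations.
#'
#' @param x strictly increasing knot abscissae.
#' @param y knot values, same length as `x`.
#' @param deriv_left,deriv_right endpoint first derivatives, or `NULL` for a
#'   natural end condition.
#' @return An object of class `"pr_spline"`; call it via [spline_eval()].
#' @seealso [spline_eval()]
#' @export
clamped_spline <- function(x, y, deriv_left = NULL, deriv_right = NULL) {
  n <- length(x)
  if (length(y) != n) stopf("x and y lengths differ")
  if (n < 2L) stopf("need at least 2 knots")
  if (any(diff(x) <= 0)) stopf("knot abscissae must be strictly increasing")
  h <- diff(x)
  if (n == 2L) {
    ## single interval: cubic Hermite with requested/linear end slopes
    s <- (y[2L] - y[1L]) / h
    d1 <- deriv_left %||% s
    d2 <- deriv_right %||% s
    ## coefficients of a + b t + c t^2 + d t^3 on [0, h]
    a <- y[1L]; b <- d1
    cc <- (3 * s - 2 * d1 - d2) / h
    dd <- (d1 + d2 - 2 * s) / h^2
    obj <- list(x = x, coef = matrix(c(a, b, cc, dd), 1L, 4L))
    class(obj) <- "pr_spline"
    return(obj)
  }
  ## solve for second derivatives M at knots (tridiagonal system)
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  for (i in 2:(n - 1L)) {
    A[i, i - 1L] <- h[i - 1L] / 6
    A[i, i]      <- (h[i - 1L] + h[i]) / 3
    A[i, i + 1L] <- h[i] / 6
    rhs[i] <- (y[i + 1L] - y[i]) / h[i] - (y[i] - y[i - 1L]) / h[i - 1L]
  }
  if (is.null(deriv_left)) {
    A[1L, 1L] <- 1
  } else {
    A[1L, 1L] <- h[1L] / 3; A[1L, 2L] <- h[1L] / 6
    rhs[1L] <- (y[2L] - y[1L]) / h[1L] - deriv_left
  }
  if (is.null(deriv_right)) {
    A[n, n] <- 1
  } else {
    A[n, n - 1L] <- h[n - 1L] / 6; A[n, n] <- h[n - 1L] / 3
    rhs[n] <- deriv_right - (y[n] - y[n - 1L]) / h[n - 1L]
  }
  M <- solve(A, rhs)
  ## per-interval polynomial coefficients about the left knot
  coef <- matrix(0, n - 1L, 4L)
  for (i in seq_len(n - 1L)) {
    coef[i, 1L] <- y[i]
    coef[i, 2L] <- (y[i + 1L] - y[i]) / h[i] - h[i] * (2 * M[i] + M[i + 1L]) / 6
    coef[i, 3L] <- M[i] / 2
    coef[i, 4L] <- (M[i + 1L] - M[i]) / (6 * h[i])
  }
  obj <- list(x = x, coef = coef)
  class(obj) <- "pr_spline"
  obj
}

#' Evaluate a spline or one of its derivatives
#'
#' @param sp a `"pr_spline"` object from [clamped_spline()].
#' @param t evaluation points (clamped evaluation is not performed; points
#'   outside the knot span use the boundary polynomial).
#' @param deriv 0, 1 or 2 for value, first or second derivative.
#' @return numeric vector of values.
#' @export
spline_eval <- function(sp, t, deriv = 0L) {
  stopifnot(inherits(sp, "pr_spline"))
  idx <- findInterval(t, sp$x, all.inside = TRUE)
  u <- t - sp$x[idx]
  co <- sp$coef[idx, , drop = FALSE]
  switch(as.character(deriv),
    "0" = co[, 1L] + u * (co[, 2L] + u * (co[, 3L] + u * co[, 4L])),
    "1" = co[, 2L] + u * (2 * co[, 3L] + 3 * u * co[, 4L]),
    "2" = 2 * co[, 3L] + 6 * u * co[, 4L],
    stopf("deriv must be 0, 1 or 2"))
}
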