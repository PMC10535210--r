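## Injury criteria: head injury criterion (HIC), chest 3 ms clip, and a
## long-bone bending-stress proxy, each compared against its tolerance
## limit (HIC 1000; long-bone fracture 124 MPa; chest limit configurable).

#' Resultant acceleration trace
#'
#' @param time sample times, s (strictly increasing).
#' @param accel resultant acceleration, g (>= 0), or a 3-column matrix of
#'   axis accelerations in g from which the resultant is computed.
#' @return object of class `"accel_trace"`.
#' @export
accel_trace <- function(time, accel) {
  if (is.matrix(accel)) accel <- sqrt(rowSums(accel^2))
  if (length(time) != length(accel)) stopf("time/accel length mismatch")
  if (length(time) < 1L) stopf("empty trace")
  if (any(diff(time) <= 0)) stopf("times must be strictly increasing")
  if (any(accel < 0)) stopf("resultant acceleration must be >= 0")
  structure(list(time = time, accel = accel), class = "accel_trace")
}

## resample to a uniform grid when needed (criteria assume uniform dt)
trace_uniform <- function(trace, dt = NULL) {
  t <- trace$time
  dts <- diff(t)
  if (is.null(dt) && length(dts) &&
      max(dts) - min(dts) < 1e-9 * max(dts)) return(trace)
  dt <- dt %||% min(dts)
  tt <- seq(t[1L], t[length(t)], by = dt)
  accel_trace(tt, stats::approx(t, trace$accel, tt)$y)
}

#' Head injury criterion
#'
#' \deqn{HIC = \max_{t_2 - t_1 \le w} (t_2-t_1)\left[\frac{1}{t_2-t_1}
#'   \int_{t_1}^{t_2} a\,dt\right]^{2.5}}
#' with `a` in g and t in s. The search is exhaustive over all sample-pair
#' windows up to `max_window` on the (uniform) sample grid, with
#' trapezoidal integrals; search resolution is therefore the trace
#' sampling interval.
#'
#' @param trace an [accel_trace()].
#' @param max_window maximum window length, s (0.036 or 0.015 customary).
#' @return list with `value`, `t1`, `t2`.
#' @export
hic <- function(trace, max_window = 0.036) {
  stopifnot(inherits(trace, "accel_trace"))
  if (length(trace$time) < 2L) stopf("trace too short for HIC")
  tr <- trace_uniform(trace)
  t <- tr$time; a <- tr$accel
  n <- length(t)
  dt <- t[2L] - t[1L]
  ct <- cumtrapz(t, a)
  wmax <- max(1L, min(n - 1L, floor(max_window / dt + 1e-9)))
  best <- c(0, t[1L], t[1L])
  for (w in seq_len(wmax)) {
    ii <- seq_len(n - w)
    integ <- ct[ii + w] - ct[ii]
    T <- w * dt
    vals <- T * (integ / T)^2.5
    k <- which.max(vals)
    if (vals[k] > best[1L]) best <- c(vals[k], t[k], t[k + w])
  }
  list(value = best[1L], t1 = best[2L], t2 = best[3L])
}

#' Chest 3 ms clip criterion
#'
#' The largest acceleration level sustained continuously for at least
#' 3 ms: the maximum over all 3 ms windows of the in-window minimum.
#'
#' @param trace an [accel_trace()].
#' @param window clip duration, s (default 0.003).
#' @return clip value, g.
#' @export
chest_3ms <- function(trace, window = 0.003) {
  stopifnot(inherits(trace, "accel_trace"))
  tr <- trace_uniform(trace)
  t <- tr$time
  if (t[length(t)] - t[1L] < window)
    stopf("trace shorter than the %g ms clip window", window * 1e3)
  dt <- t[2L] - t[1L]
  k <- max(2L, ceiling(window / dt - 1e-9) + 1L)
  max(sliding_min(tr$accel, k))
}

#' Long-bone peak bending stress proxy
#'
#' Beam-theory surrogate for the finite-element bone stress: the peak
#' transverse contact force is applied mid-span to a simply supported
#' tube, so \eqn{M = F L / 4}, \eqn{\sigma = M c / I} with c the outer
#' radius and \eqn{I = \pi (r_o^4 - r_i^4)/4}.
#'
#' @param force transverse force history or a single peak force, N.
#' @param length bone length, m.
#' @param r_outer,r_inner outer/inner radii, m (`r_inner = 0` for a solid
#'   rod).
#' @return peak stress, MPa.
#' @export
long_bone_stress <- function(force, length, r_outer, r_inner = 0) {
  check_number(length, "length", 0, strict_lower = TRUE)
  check_number(r_outer, "r_outer", 0, strict_lower = TRUE)
  check_number(r_inner, "r_inner", 0)
  if (r_inner >= r_outer) stopf("r_inner must be < r_outer")
  Fpk <- max(abs(force))
  M <- Fpk * length / 4
  I <- pi * (r_outer^4 - r_inner^4) / 4
  M * r_outer / I / 1e6
}

## documented tibia/femur tube presets scaled to stature (m)
bone_geometry <- function(stature = 1.74) {
  list(
    tibia = list(length = 0.22 * stature, r_outer = 0.011 * stature / 1.74,
                 r_inner = 0.006 * stature / 1.74),
    femur = list(length = 0.245 * stature, r_outer = 0.0135 * stature / 1.74,
                 r_inner = 0.007 * stature / 1.74))
}

#' Assemble an injury report against tolerance limits
#'
#' Flags the head when HIC exceeds 1000 and a long bone when its peak
#' bending stress exceeds the 124 MPa fracture tolerance; the chest
#' 3 ms threshold is configurable (no universal numeric limit is
#' asserted by default).
#'
#' @param hic_result list from [hic()] (or a bare HIC value).
#' @param chest_value chest 3 ms clip, g (optional).
#' @param bone_stress named numeric of peak bone stresses, MPa (optional).
#' @param hic_limit,bone_limit_mpa,chest_limit tolerance limits.
#' @return object of class `"injury_report"`: data.frame `criteria` with
#'   `criterion`, `value`, `limit`, `exceeded`, plus the HIC window.
#' @export
assess_injury <- function(hic_result, chest_value = NA_real_,
                          bone_stress = NULL, hic_limit = 1000,
                          bone_limit_mpa = 124, chest_limit = NA_real_) {
  if (is.numeric(hic_result))
    hic_result <- list(value = hic_result, t1 = NA_real_, t2 = NA_real_)
  crit <- data.frame(
    criterion = "HIC", value = hic_result$value, limit = hic_limit,
    exceeded = hic_result$value > hic_limit, stringsAsFactors = FALSE)
  if (!is.na(chest_value))
    crit <- rbind(crit, data.frame(
      criterion = "chest_3ms_g", value = chest_value, limit = chest_limit,
      exceeded = !is.na(chest_limit) && chest_value > chest_limit,
      stringsAsFactors = FALSE))
  for (b in names(bone_stress))
    crit <- rbind(crit, data.frame(
      criterion = paste0(b, "_stress_MPa"), value = bone_stress[[b]],
      limit = bone_limit_mpa, exceeded = bone_stress[[b]] > bone_limit_mpa,
      stringsAsFactors = FALSE))
  structure(list(criteria = crit, hic_window = c(hic_result$t1,
                                                 hic_result$t2)),
            class = "injury_report")
}

#' @export
print.injury_report <- function(x, ...) {
  cat("Injury criteria vs tolerance limits\n")
  df <- x$criteria
  df$value <- signif(df$value, 5)
  print(df, row.names = FALSE)
  if (!any(is.na(x$hic_window)))
    cat(sprintf("  HIC window: [%.4f, %.4f] s\n",
                x$hic_window[1L], x$hic_window[2L]))
  invisible(x)
}

#' Read an acceleration trace CSV
#'
#' Accepts either `time_s, resultant_g` or `time_s, ax_g, ay_g, az_g`.
#'
#' @param path file path.
#' @return an [accel_trace()].
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  if ("resultant_g" %in% names(df))
    accel_trace(df$time_s, df$resultant_g)
  else
    accel_trace(df$time_s, as.matrix(df[, c("ax_g", "ay_g", "az_g")]))
}
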