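## Spring-loaded inverted pendulum ("virtual leg") running model.
##
## The pedestrian centroid is a point mass on a massless prismatic spring
## leg.  In stance the generalized coordinates are the leg length q_r and
## the angle q_theta between the leg and the plumb line (positive when the
## foothold trails the centre of mass in the running direction +x), with
##   COM = foothold + q_r * (sin q_theta, cos q_theta).
## In flight the centroid is ballistic.  A periodic alternation of the two
## phases is the running gait; the commanded forward speed is met by a
## shooting search over the touchdown angle.

#' Virtual-leg (SLIP) model parameters
#'
#' @param mass body mass, kg.
#' @param stiffness leg spring stiffness \eqn{k_r}, N/m.
#' @param rest_length uncompressed virtual-leg length \eqn{q_{r0}}, m.
#'   Defaults to `0.53 * stature` when `stature` is given instead.
#' @param touchdown_angle angle between the virtual leg and the plumb line
#'   at touchdown, rad (positive magnitude; the foothold is placed ahead of
#'   the centre of mass). Usually left `NA` and solved for by [slip_gait()].
#' @param gravity gravitational acceleration, m/s^2.
#' @param stature optional stature, m, used only to default `rest_length`.
#' @return object of class `"slip_params"`.
#' @export
slip_params <- function(mass, stiffness = 4e4, rest_length = NULL,
                        touchdown_angle = NA_real_, gravity = GRAV,
                        stature = NULL) {
  check_number(mass, "mass", 0, strict_lower = TRUE)
  check_number(stiffness, "stiffness", 0, strict_lower = TRUE)
  if (is.null(rest_length)) {
    if (is.null(stature)) stopf("give rest_length or stature")
    rest_length <- 0.53 * stature
  }
  check_number(rest_length, "rest_length", 0, strict_lower = TRUE)
  check_number(gravity, "gravity", 0, strict_lower = TRUE)
  if (!is.na(touchdown_angle) && abs(touchdown_angle) >= pi / 2)
    stopf("|touchdown_angle| must be < pi/2")
  structure(list(m = mass, k_r = stiffness, q_r0 = rest_length,
                 g = gravity, touchdown_angle = touchdown_angle),
            class = "slip_params")
}

#' Stance state of the virtual-leg model
#'
#' @param q_r leg length m; `q_theta` leg angle from plumb line rad;
#'   `dq_r`, `dq_theta` their rates; `foothold` ground contact point (x, z);
#'   `time` s.
#' @param q_theta,dq_r,dq_theta,foothold,time see above.
#' @return list of class `"slip_state"` with derived `com` and `vel`.
#' @export
slip_state <- function(q_r, q_theta, dq_r, dq_theta,
                       foothold = c(0, 0), time = 0) {
  if (q_r <= 0) stopf("singular configuration: q_r must be > 0")
  com <- foothold + q_r * c(sin(q_theta), cos(q_theta))
  vel <- c(dq_r * sin(q_theta) + q_r * cos(q_theta) * dq_theta,
           dq_r * cos(q_theta) - q_r * sin(q_theta) * dq_theta)
  structure(list(q_r = q_r, q_theta = q_theta, dq_r = dq_r,
                 dq_theta = dq_theta, phase = "stance",
                 foothold = foothold, com = com, vel = vel, time = time),
            class = "slip_state")
}

#' Stance-phase accelerations of the virtual leg
#'
#' Solves the stance equations of motion for the second derivatives:
#' \deqn{\ddot q_\theta = (g \sin q_\theta - 2\dot q_\theta \dot q_r)/q_r}
#' \deqn{\ddot q_r = q_r \dot q_\theta^2 - g\cos q_\theta - (k_r/m)(q_r - q_{r0})}
#'
#' @param state a `"slip_state"` (or list with `q_r`, `q_theta`, `dq_r`,
#'   `dq_theta`).
#' @param params a [slip_params()] object.
#' @return named numeric `c(ddq_r, ddq_theta)`.
#' @export
stance_derivatives <- function(state, params) {
  if (state$q_r <= 0) stopf("singular configuration: q_r must be > 0")
  with(c(state[c("q_r", "q_theta", "dq_r", "dq_theta")], unclass(params)), {
    ddq_theta <- (g * sin(q_theta) - 2 * dq_theta * dq_r) / q_r
    ddq_r <- q_r * dq_theta^2 - g * cos(q_theta) - (k_r / m) * (q_r - q_r0)
    c(ddq_r = ddq_r, ddq_theta = ddq_theta)
  })
}

## mechanical energy per unit state (stance convention, foothold at z = 0)
slip_energy <- function(q_r, q_theta, dq_r, dq_theta, params) {
  v2 <- dq_r^2 + (q_r * dq_theta)^2
  0.5 * params$m * v2 + params$m * params$g * q_r * cos(q_theta) +
    0.5 * params$k_r * (q_r - params$q_r0)^2
}

#' Integrate one stance phase of the virtual leg
#'
#' Integrates the stance dynamics with adaptive error control
#' ([deSolve::lsodar()]) from a touchdown state until the liftoff event
#' (\eqn{q_r} back at \eqn{q_{r0}} with \eqn{\dot q_r > 0}, i.e. zero
#' spring force) or until the centroid reaches the ground (flagged as a
#' `"fall"` event, not an error).
#'
#' @param initial a touchdown [slip_state()] (with `q_r = q_r0` and
#'   `dq_r < 0`).
#' @param params [slip_params()].
#' @param tol relative integration tolerance (default `1e-8`).
#' @param dt_sample output sampling interval, s.
#' @param t_max safety horizon, s.
#' @return data.frame of class `"phase_trajectory"` with columns `time`,
#'   `phase`, `q_r`, `q_theta`, `dq_r`, `dq_theta`, `com_x`, `com_z`, `vx`,
#'   `vz`; attributes `terminating_event` (`"liftoff"` or `"fall"`) and
#'   `foothold`.
#' @export
integrate_stance <- function(initial, params, tol = 1e-8,
                             dt_sample = 1e-3, t_max = 2) {
  p <- params
  if (initial$dq_r >= 0)
    stopf("touchdown state must compress the leg (dq_r < 0)")
  deriv <- function(t, y, parms) {
    st <- list(q_r = y[1L], q_theta = y[2L], dq_r = y[3L], dq_theta = y[4L])
    dd <- stance_derivatives(st, p)
    list(c(y[3L], y[4L], dd[["ddq_r"]], dd[["ddq_theta"]]))
  }
  root <- function(t, y, parms) {
    c(y[1L] - p$q_r0,          # liftoff candidate (checked for dq_r > 0)
      y[1L] * cos(y[2L]))      # centroid at ground height -> fall
  }
  y0 <- c(initial$q_r, initial$q_theta, initial$dq_r, initial$dq_theta)
  ## tiny fixed pre-step so the liftoff root (zero at touchdown by
  ## construction) is not triggered at t = 0
  pre <- 1e-6
  k1 <- deriv(0, y0, NULL)[[1L]]
  k2 <- deriv(0, y0 + pre / 2 * k1, NULL)[[1L]]
  k3 <- deriv(0, y0 + pre / 2 * k2, NULL)[[1L]]
  k4 <- deriv(0, y0 + pre * k3, NULL)[[1L]]
  y1 <- y0 + pre / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  t_ev <- NA_real_
  event <- NULL
  y_acc <- rbind(c(0, y0))
  t_from <- pre
  y_from <- y1
  repeat {
    times <- unique(c(t_from, seq(t_from, t_max, by = dt_sample), t_max))
    sol <- deSolve::lsodar(y_from, times, deriv, parms = NULL,
                           rtol = tol, atol = tol * 1e-2, rootfunc = root)
    y_acc <- rbind(y_acc, unname(sol[, , drop = FALSE]))
    t_end <- sol[nrow(sol), 1L]
    y_end <- sol[nrow(sol), -1L]
    iroot <- attr(sol, "iroot")
    if (!is.null(iroot) && any(iroot != 0)) {
      if (y_end[1L] * cos(y_end[2L]) <= tol * 10) { event <- "fall"; break }
      if (abs(y_end[1L] - p$q_r0) < 1e-6 * p$q_r0 && y_end[3L] > 0) {
        event <- "liftoff"; break
      }
      ## spurious root (e.g. q_r crossing q_r0 downwards); continue past it
      t_from <- t_end + pre
      k1 <- deriv(t_end, y_end, NULL)[[1L]]
      y_from <- y_end + pre * k1
      if (t_from >= t_max) { event <- "timeout"; break }
    } else { event <- "timeout"; break }
  }
  if (identical(event, "timeout"))
    stopf("stance integration did not reach liftoff within %g s", t_max)
  df <- as.data.frame(y_acc)
  names(df) <- c("time", "q_r", "q_theta", "dq_r", "dq_theta")
  df <- df[!duplicated(df$time), , drop = FALSE]
  df <- df[order(df$time), , drop = FALSE]
  fh <- initial$foothold
  df$phase <- "stance"
  df$com_x <- fh[1L] + df$q_r * sin(df$q_theta)
  df$com_z <- fh[2L] + df$q_r * cos(df$q_theta)
  df$vx <- df$dq_r * sin(df$q_theta) + df$q_r * cos(df$q_theta) * df$dq_theta
  df$vz <- df$dq_r * cos(df$q_theta) - df$q_r * sin(df$q_theta) * df$dq_theta
  df$time <- df$time + initial$time
  rownames(df) <- NULL
  structure(df[, c("time", "phase", "q_r", "q_theta", "dq_r", "dq_theta",
                   "com_x", "com_z", "vx", "vz")],
            terminating_event = event, foothold = fh,
            class = c("phase_trajectory", "data.frame"))
}

#' Integrate one flight (aerial) phase
#'
#' The centroid follows the ballistic closed form (horizontal momentum
#' conserved, constant gravitational acceleration); the phase terminates at
#' the touchdown event where the leg, swung forward to the touchdown angle
#' at its rest length, meets the ground, i.e. when the centroid descends to
#' height \eqn{q_{r0}\cos\alpha}.
#'
#' @param initial list with `com` (x, z), `vel` (vx, vz), `time`; e.g. the
#'   last row of a stance trajectory.
#' @param params [slip_params()] with a finite `touchdown_angle`.
#' @param dt_sample output sampling interval, s.
#' @return `"phase_trajectory"` data.frame (see [integrate_stance()]);
#'   terminating event `"touchdown"`, `"apex"` never terminal, `"fall"`
#'   when the apex stays below the touchdown leg height and the centroid
#'   would hit the ground.
#' @export
integrate_flight <- function(initial, params, dt_sample = 1e-3) {
  alpha <- params$touchdown_angle
  if (is.na(alpha)) stopf("params$touchdown_angle must be set for flight")
  g <- params$g
  x0 <- initial$com[1L]; z0 <- initial$com[2L]
  vx <- initial$vel[1L]; vz0 <- initial$vel[2L]
  z_td <- params$q_r0 * cos(alpha)
  disc <- vz0^2 + 2 * g * (z0 - z_td)
  if (disc >= 0 && (z0 > z_td || vz0 > 0)) {
    t_end <- (vz0 + sqrt(disc)) / g
    event <- "touchdown"
  } else if (z0 <= z_td && vz0 <= 0) {
    t_end <- 0
    event <- "touchdown"
  } else {
    ## apex below touchdown height: fall to the ground
    t_end <- (vz0 + sqrt(vz0^2 + 2 * g * z0)) / g
    event <- "fall"
  }
  tt <- unique(c(seq(0, t_end, by = dt_sample), t_end))
  df <- data.frame(
    time = tt + initial$time, phase = "flight",
    q_r = params$q_r0, q_theta = -alpha,
    dq_r = NA_real_, dq_theta = NA_real_,
    com_x = x0 + vx * tt,
    com_z = z0 + vz0 * tt - 0.5 * g * tt^2,
    vx = vx, vz = vz0 - g * tt)
  structure(df, terminating_event = event, foothold = c(NA_real_, NA_real_),
            class = c("phase_trajectory", "data.frame"))
}

## one apex-to-apex step: returns next apex (z, vx) and bookkeeping,
## or NULL if the step falls
slip_step_map <- function(apex_z, apex_vx, alpha, params, tol = 1e-8,
                          dt_sample = 1e-3) {
  p <- params
  p$touchdown_angle <- alpha
  z_td <- p$q_r0 * cos(alpha)
  if (apex_z < z_td) return(NULL)
  g <- p$g
  ## flight down from apex to touchdown (closed form)
  t_down <- sqrt(2 * (apex_z - z_td) / g)
  vz_td <- -g * t_down
  qt <- -alpha
  dq_r <- apex_vx * sin(qt) + vz_td * cos(qt)
  dq_th <- (apex_vx * cos(qt) - vz_td * sin(qt)) / p$q_r0
  if (dq_r >= 0) return(NULL)
  st <- slip_state(p$q_r0, qt, dq_r, dq_th, foothold = c(0, 0), time = 0)
  tr <- tryCatch(integrate_stance(st, p, tol = tol, dt_sample = dt_sample),
                 error = function(e) NULL)
  if (is.null(tr) || attr(tr, "terminating_event") != "liftoff") return(NULL)
  n <- nrow(tr)
  vx_lo <- tr$vx[n]; vz_lo <- tr$vz[n]
  if (vz_lo <= 0) return(NULL)
  z_lo <- tr$com_z[n]
  t_up <- vz_lo / g
  list(z_next = z_lo + vz_lo^2 / (2 * g), vx_next = vx_lo,
       stance = tr, t_down = t_down, t_up = t_up,
       x_advance = apex_vx * t_down + (tr$com_x[n] - tr$com_x[1L]) +
         vx_lo * t_up,
       period = t_down + tr$time[n] + t_up)
}

#' Find a periodic running gait at a commanded speed
#'
#' Shooting search for a limit cycle of the virtual-leg model: for a given
#' touchdown angle the apex forward speed is solved so that the apex height
#' recurs step to step (energy conservation then makes the whole apex state
#' recur), and the touchdown angle is solved so that the mean forward speed
#' matches `target_speed` within 1 %.
#'
#' @param params [slip_params()]; its `touchdown_angle` is ignored (it is
#'   the shooting variable).
#' @param target_speed commanded mean forward speed, m/s.
#' @param tol solver tolerance for integration and the periodicity
#'   residual.
#' @param hop apex clearance above the touchdown height, m. Sets the flight
#'   intensity of the gait.
#' @param alpha_range search bracket for the touchdown angle, rad.
#' @return object of class `"slip_gait"`: the stance and flight
#'   trajectories of one cycle (touchdown to touchdown), `step_length`,
#'   `step_period`, `mean_forward_speed`, `apex_height`, the solved
#'   `touchdown_angle` and apex state.
#' @export
slip_gait <- function(params, target_speed, tol = 1e-8, hop = 0.045,
                      alpha_range = c(0.08, 0.85)) {
  check_number(target_speed, "target_speed", 0, strict_lower = TRUE)
  solve_apex_vx <- function(alpha) {
    z_a <- params$q_r0 * cos(alpha) + hop
    f <- function(vx) {
      s <- slip_step_map(z_a, vx, alpha, params, tol = tol)
      if (is.null(s)) return(NA_real_)
      s$z_next - z_a
    }
    grid <- seq(max(0.6, 0.4 * target_speed), 3 * target_speed + 2,
                length.out = 25)
    vals <- vapply(grid, f, 0)
    ok <- which(is.finite(vals))
    if (length(ok) < 2L) return(NULL)
    sc <- NULL
    for (i in seq_len(length(ok) - 1L)) {
      a <- ok[i]; b <- ok[i + 1L]
      if (b == a + 1L && vals[a] * vals[b] <= 0) { sc <- c(a, b); break }
    }
    if (is.null(sc)) return(NULL)
    r <- stats::uniroot(f, c(grid[sc[1L]], grid[sc[2L]]), tol = 1e-10)
    list(vx = r$root, z_a = z_a)
  }
  speed_of_alpha <- function(alpha) {
    ap <- solve_apex_vx(alpha)
    if (is.null(ap)) return(NULL)
    s <- slip_step_map(ap$z_a, ap$vx, alpha, params, tol = tol)
    if (is.null(s)) return(NULL)
    list(speed = s$x_advance / s$period, alpha = alpha, apex = ap, step = s)
  }
  agrid <- seq(alpha_range[1L], alpha_range[2L], length.out = 14)
  cand <- lapply(agrid, function(a) speed_of_alpha(a))
  sp <- vapply(cand, function(z) if (is.null(z)) NA_real_ else z$speed, 0)
  resid <- sp - target_speed
  ok <- which(is.finite(resid))
  sc <- NULL
  for (i in seq_len(max(0, length(ok) - 1L))) {
    a <- ok[i]; b <- ok[i + 1L]
    if (b == a + 1L && resid[a] * resid[b] <= 0) { sc <- c(a, b); break }
  }
  if (is.null(sc))
    stopf(paste0("no periodic gait at %.3g m/s in touchdown-angle bracket ",
                 "[%.2f, %.2f]; speed residuals spanned [%.3g, %.3g]"),
          target_speed, alpha_range[1L], alpha_range[2L],
          min(resid, na.rm = TRUE), max(resid, na.rm = TRUE))
  r <- stats::uniroot(function(a) {
    z <- speed_of_alpha(a)
    if (is.null(z)) return(NA_real_)
    z$speed - target_speed
  }, c(agrid[sc[1L]], agrid[sc[2L]]), tol = 1e-7)
  sol <- speed_of_alpha(r$root)
  alpha <- sol$alpha
  p <- params; p$touchdown_angle <- alpha
  ## assemble one cycle starting at touchdown (com_x = 0)
  z_td <- p$q_r0 * cos(alpha)
  t_down <- sol$step$t_down
  vz_td <- -p$g * t_down
  qt0 <- -alpha
  st0 <- slip_state(p$q_r0, qt0,
                    sol$apex$vx * sin(qt0) + vz_td * cos(qt0),
                    (sol$apex$vx * cos(qt0) - vz_td * sin(qt0)) / p$q_r0,
                    foothold = c(p$q_r0 * sin(alpha), 0), time = 0)
  stance <- integrate_stance(st0, p, tol = tol)
  n <- nrow(stance)
  lift <- list(com = c(stance$com_x[n], stance$com_z[n]),
               vel = c(stance$vx[n], stance$vz[n]), time = stance$time[n])
  flight <- integrate_flight(lift, p)
  m <- nrow(flight)
  structure(list(
    params = p, touchdown_angle = alpha,
    apex_height = sol$apex$z_a, apex_speed = sol$apex$vx,
    stance = stance, flight = flight,
    step_length = flight$com_x[m] - stance$com_x[1L],
    step_period = flight$time[m],
    mean_forward_speed = (flight$com_x[m] - stance$com_x[1L]) /
      flight$time[m],
    target_speed = target_speed, hop = hop, tol = tol),
    class = "slip_gait")
}

#' Tile a periodic gait cycle over several steps
#'
#' @param gait a [slip_gait()] object.
#' @param n_steps number of steps (>= 1).
#' @param dt_out output sampling interval, s.
#' @return `"phase_trajectory"` data.frame resampled at `dt_out`, with
#'   continuous centroid position and velocity across phase joins.
#' @export
compose_gait <- function(gait, n_steps = 1L, dt_out = 1e-3) {
  stopifnot(inherits(gait, "slip_gait"))
  if (n_steps < 1L) stopf("n_steps must be >= 1")
  cyc <- rbind(as.data.frame(gait$stance), as.data.frame(gait$flight))
  cyc <- cyc[!duplicated(cyc$time), ]
  interp <- function(col, t) stats::approx(cyc$time, cyc[[col]], t,
                                           rule = 2)$y
  out <- NULL
  for (k in seq_len(n_steps) - 1L) {
    tt <- seq(0, gait$step_period, by = dt_out)
    if (k < n_steps - 1L) tt <- tt[tt < gait$step_period]
    seg <- data.frame(
      time = tt + k * gait$step_period,
      phase = ifelse(tt <= gait$stance$time[nrow(gait$stance)],
                     "stance", "flight"),
      q_r = interp("q_r", tt), q_theta = interp("q_theta", tt),
      dq_r = interp("dq_r", tt), dq_theta = interp("dq_theta", tt),
      com_x = interp("com_x", tt) + k * gait$step_length,
      com_z = interp("com_z", tt),
      vx = interp("vx", tt), vz = interp("vz", tt))
    out <- rbind(out, seg)
  }
  out <- out[!duplicated(out$time), ]
  rownames(out) <- NULL
  structure(out, terminating_event = "touchdown",
            class = c("phase_trajectory", "data.frame"))
}

#' @export
print.slip_gait <- function(x, ...) {
  cat("Periodic virtual-leg running gait\n")
  cat(sprintf("  mean forward speed : %.4f m/s (target %.4f)\n",
              x$mean_forward_speed, x$target_speed))
  cat(sprintf("  touchdown angle    : %.4f rad\n", x$touchdown_angle))
  cat(sprintf("  step length/period : %.3f m / %.4f s\n",
              x$step_length, x$step_period))
  cat(sprintf("  apex height        : %.3f m\n", x$apex_height))
  invisible(x)
}

#' @export
summary.slip_gait <- function(object, ...) {
  st <- object$stance
  E <- slip_energy(st$q_r, st$q_theta, st$dq_r, st$dq_theta, object$params)
  out <- list(gait = object,
              stance_duration = st$time[nrow(st)] - st$time[1L],
              flight_duration = object$step_period -
                (st$time[nrow(st)] - st$time[1L]),
              duty_factor = (st$time[nrow(st)] - st$time[1L]) /
                object$step_period,
              max_compression = object$params$q_r0 - min(st$q_r),
              energy_drift = (max(E) - min(E)) / mean(E))
  class(out) <- "summary.slip_gait"
  out
}

#' @export
print.summary.slip_gait <- function(x, ...) {
  print(x$gait)
  cat(sprintf("  stance/flight      : %.4f s / %.4f s (duty %.2f)\n",
              x$stance_duration, x$flight_duration, x$duty_factor))
  cat(sprintf("  max leg compression: %.3f m (%.1f%% of rest length)\n",
              x$max_compression,
              100 * x$max_compression / x$gait$params$q_r0))
  cat(sprintf("  stance energy drift: %.2e (relative)\n", x$energy_drift))
  invisible(x)
}

#' @export
plot.slip_gait <- function(x, n_steps = 3L, ...) {
  tr <- compose_gait(x, n_steps)
  graphics::plot(tr$com_x, tr$com_z, type = "l", xlab = "x (m)",
                 ylab = "z (m)", main = "Centroid trajectory", ...)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Export a composed gait trajectory as CSV
#'
#' Columns: `time_s, phase, com_x_m, com_z_m, vx_mps, vz_mps, q_r_m,
#' q_theta_rad`.
#'
#' @param traj a `"phase_trajectory"` (e.g. from [compose_gait()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gait_csv <- function(traj, path) {
  df <- data.frame(time_s = traj$time, phase = traj$phase,
                   com_x_m = traj$com_x, com_z_m = traj$com_z,
                   vx_mps = traj$vx, vz_mps = traj$vz,
                   q_r_m = traj$q_r, q_theta_rad = traj$q_theta)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
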