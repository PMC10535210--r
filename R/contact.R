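## Pedestrian-vehicle and pedestrian-ground contact.
##
## Narrow phase: every segment capsule is sampled as spheres (endpoints +
## midpoint) and tested against the ground plane and the vehicle front
## profile (a planar outline extruded across the vehicle width, the facet
## surface carrying per-region contact characteristics).  Normal force
## follows a piecewise-linear penetration-stiffness loading curve with a
## hysteretic unloading branch; tangential force is regularized Coulomb
## friction.

#' Penetration-stiffness contact curve with hysteresis
#'
#' @param penetration increasing penetrations, m, starting at 0.
#' @param force non-decreasing forces, N, starting at 0.
#' @param hysteresis unloading factor in (0, 1]: on the unloading branch
#'   (penetration rate < 0) the force is `hysteresis` times the loading
#'   force at equal penetration, so each load/unload cycle dissipates a
#'   non-negative loop area.
#' @return object of class `"contact_curve"`.
#' @export
contact_curve <- function(penetration, force, hysteresis = 0.5) {
  if (length(penetration) != length(force) || length(penetration) < 2L)
    stopf("penetration and force must be equal-length vectors (>= 2)")
  if (penetration[1L] != 0 || force[1L] != 0)
    stopf("contact curve must start at (0, 0)")
  if (any(diff(penetration) <= 0)) stopf("penetrations must increase")
  if (any(diff(force) < 0)) stopf("loading curve must be non-decreasing")
  check_number(hysteresis, "hysteresis", 0, 1, strict_lower = TRUE)
  structure(list(penetration = penetration, force = force,
                 hysteresis = hysteresis),
            class = "contact_curve")
}

#' Loading-branch force of a contact curve
#'
#' Penetrations beyond the tabulated domain extrapolate the final slope
#' (flagged via the `"extrapolated"` attribute).
#'
#' @param curve a [contact_curve()].
#' @param penetration penetration depth(s), m (>= 0).
#' @return force(s), N.
#' @export
curve_force <- function(curve, penetration) {
  p <- curve$penetration; f <- curve$force
  n <- length(p)
  out <- stats::approx(p, f, pmax(penetration, 0), rule = 2)$y
  over <- penetration > p[n]
  if (any(over)) {
    slope <- (f[n] - f[n - 1L]) / (p[n] - p[n - 1L])
    out[over] <- f[n] + slope * (penetration[over] - p[n])
    attr(out, "extrapolated") <- TRUE
  }
  out
}

#' Friction coefficient set for the scene
#'
#' @param car_ground,ped_ground,car_ped Coulomb coefficients.
#' @return object of class `"friction_spec"`.
#' @export
friction_spec <- function(car_ground = 0.7, ped_ground = 0.6,
                          car_ped = 0.3) {
  for (v in c(car_ground, ped_ground, car_ped))
    check_number(v, "friction coefficient", 0)
  structure(list(mu_car_ground = car_ground, mu_ped_ground = ped_ground,
                 mu_car_ped = car_ped), class = "friction_spec")
}

#' Simplified vehicle front profile
#'
#' Planar outline of the front of the vehicle as ordered stations in the
#' vehicle (x, z) plane (x forward from the bumper face, z up from the
#' ground), extruded across the width. Each outline segment carries a
#' region label that selects its contact curve.
#'
#' @param stations data.frame with columns `name`, `x`, `z` ordered by
#'   increasing z.
#' @param width vehicle width, m.
#' @param mass vehicle mass, kg.
#' @param curves named list of [contact_curve()] per region label.
#' @param regions region label per outline segment
#'   (`length(regions) == nrow(stations) - 1`).
#' @return object of class `"vehicle_profile"`.
#' @export
vehicle_profile <- function(stations, width, mass, curves, regions) {
  stopifnot(is.data.frame(stations),
            all(c("name", "x", "z") %in% names(stations)))
  if (any(diff(stations$z) < 0)) stopf("stations must be ordered in z")
  check_number(width, "width", 0, strict_lower = TRUE)
  if (length(regions) != nrow(stations) - 1L)
    stopf("need one region label per outline segment")
  missing <- setdiff(unique(regions), names(curves))
  if (length(missing))
    stopf("no contact curve for region(s): %s",
          paste(missing, collapse = ", "))
  structure(list(stations = stations, width = width, mass = mass,
                 curves = curves, regions = regions),
            class = "vehicle_profile")
}

#' Sedan-like vehicle preset
#'
#' Documented synthetic front-profile geometry and per-region
#' penetration-stiffness presets (stiff bumper, medium hood, compliant
#' windshield); none of the numeric curve values is a measured vehicle
#' characteristic.
#'
#' @param speed initial speed, m/s (stored for convenience).
#' @return a [vehicle_profile()] with a `speed` field.
#' @export
sedan_profile <- function(speed = 18.5) {
  stations <- data.frame(
    name = c("bumper_lower", "bumper_upper", "hood_leading", "hood_rear",
             "windshield_base", "windshield_top", "roof_rear"),
    x = c(0.00, -0.02, -0.10, -0.85, -0.90, -1.55, -2.50),
    z = c(0.35, 0.55, 0.72, 0.92, 0.95, 1.45, 1.48),
    stringsAsFactors = FALSE)
  curves <- list(
    bumper = contact_curve(c(0, 0.03, 0.10, 0.25, 0.50),
                           c(0, 4000, 15000, 30000, 36000),
                           hysteresis = 0.45),
    hood = contact_curve(c(0, 0.05, 0.20, 0.50, 0.90),
                         c(0, 3000, 12000, 25000, 30000),
                         hysteresis = 0.40),
    windshield = contact_curve(c(0, 0.05, 0.20, 0.50, 0.90),
                               c(0, 2000, 8000, 18000, 22000),
                               hysteresis = 0.35))
  prof <- vehicle_profile(stations, width = 1.80, mass = 1500,
                          curves = curves,
                          regions = c("bumper", "bumper", "hood", "hood",
                                      "windshield", "windshield"))
  prof$speed <- speed
  prof
}

#' Ground contact curve preset
#'
#' @return a [contact_curve()] for the road surface.
#' @export
ground_curve <- function() {
  contact_curve(c(0, 0.05, 0.20, 0.50), c(0, 10000, 70000, 100000),
                hysteresis = 0.25)
}

## closest point on the profile polyline to (x, z); returns the closest
## point, the outward unit normal of its segment, the signed distance
## (positive outside the solid) and the segment region
profile_closest <- function(profile, x, z) {
  st <- profile$stations
  best <- NULL
  ref <- c(1, 1) / sqrt(2)
  for (s in seq_len(nrow(st) - 1L)) {
    p1 <- c(st$x[s], st$z[s]); p2 <- c(st$x[s + 1L], st$z[s + 1L])
    d <- p2 - p1
    L2 <- sum(d^2)
    tpar <- if (L2 == 0) 0 else
      min(1, max(0, sum((c(x, z) - p1) * d) / L2))
    cp <- p1 + tpar * d
    dist <- sqrt(sum((c(x, z) - cp)^2))
    n <- c(d[2L], -d[1L]); nl <- sqrt(sum(n^2))
    if (nl == 0) n <- c(1, 0) else n <- n / nl
    if (sum(n * ref) < 0) n <- -n
    if (is.null(best) || dist < best$dist)
      best <- list(cp = cp, n = n, dist = dist,
                   region = profile$regions[s])
  }
  side <- sum((c(x, z) - best$cp) * best$n)
  best$signed <- if (side >= 0) best$dist else -best$dist
  best
}

#' Detect pedestrian contacts against ground and vehicle
#'
#' Sphere samples of every segment capsule are tested against the ground
#' plane and (if given) the vehicle front profile in the vehicle frame.
#' Every reported penetration is positive; normals are unit vectors
#' pointing from the surface into the body.
#'
#' @param model an [mb_model()].
#' @param state an `"mb_state"`.
#' @param profile optional [vehicle_profile()].
#' @param vehicle_state optional list with `position` (x, y of the bumper
#'   reference, m), `heading` (rad), `velocity` (world, m/s).
#' @param ground_z ground height, m.
#' @return data.frame with one row per contact: `seg`, `surface`
#'   (`"ground"`/`"vehicle"`), `region`, surface contact point
#'   `px, py, pz`, capsule-axis application point `cx, cy, cz` (forces
#'   are applied on the axis so rubbing cannot torque a segment about its
#'   own long axis), normal `nx, ny, nz`, `penetration` (m), relative velocity
#'   `vrx, vry, vrz` (body relative to surface, m/s) and `radius`.
#' @export
detect_contacts <- function(model, state, profile = NULL,
                            vehicle_state = NULL, ground_z = 0) {
  pts <- capsule_points(model, state$q, state$qd)
  detect_contacts_pts(pts, profile, vehicle_state, ground_z)
}

detect_contacts_pts <- function(pts, profile = NULL, vehicle_state = NULL,
                                ground_z = 0) {
  segs <- attr(pts, "seg"); radii <- attr(pts, "radius")
  vels <- attr(pts, "vel")
  if (is.null(vels)) vels <- matrix(0, nrow(pts), 3L)
  np <- nrow(pts)
  cap <- 2L * np
  seg_o <- character(cap); surf_o <- character(cap); reg_o <- character(cap)
  num <- matrix(0, cap, 13L)   # px py pz cx cy cz nx ny nz pen vrx vry vrz
  rad_o <- numeric(cap)
  k <- 0L
  ## ground plane
  pen_g <- radii - (pts[, 3L] - ground_z)
  for (i in which(pen_g > 0)) {
    k <- k + 1L
    seg_o[k] <- segs[i]; surf_o[k] <- "ground"; reg_o[k] <- "ground"
    num[k, ] <- c(pts[i, 1L], pts[i, 2L], ground_z,
                  pts[i, 1L], pts[i, 2L], pts[i, 3L],
                  0, 0, 1, pen_g[i], vels[i, 1L], vels[i, 2L],
                  vels[i, 3L])
    rad_o[k] <- radii[i]
  }
  if (!is.null(profile) && !is.null(vehicle_state)) {
    psi <- vehicle_state$heading
    cp <- cos(psi); sp <- sin(psi)
    pos <- vehicle_state$position
    vv <- vehicle_state$velocity
    zr <- range(profile$stations$z)
    xr <- range(profile$stations$x)
    ## vehicle-frame coordinates of all sample points at once
    dx <- pts[, 1L] - pos[1L]; dy <- pts[, 2L] - pos[2L]
    xv <- cp * dx + sp * dy
    yv <- -sp * dx + cp * dy
    zv <- pts[, 3L]
    cand <- which(abs(yv) <= profile$width / 2 + radii &
                    zv >= zr[1L] - radii & zv <= zr[2L] + 2 * radii &
                    xv <= xr[2L] + radii & xv >= xr[1L] - 1)
    for (i in cand) {
      pc <- profile_closest(profile, xv[i], zv[i])
      pen <- radii[i] - pc$signed
      if (pen <= 0) next
      k <- k + 1L
      seg_o[k] <- segs[i]; surf_o[k] <- "vehicle"; reg_o[k] <- pc$region
      num[k, ] <- c(pos[1L] + cp * pc$cp[1L], pos[2L] + sp * pc$cp[1L],
                    pc$cp[2L],
                    pts[i, 1L], pts[i, 2L], pts[i, 3L],
                    cp * pc$n[1L], sp * pc$n[1L], pc$n[2L], pen,
                    vels[i, 1L] - vv[1L], vels[i, 2L] - vv[2L],
                    vels[i, 3L] - vv[3L])
      rad_o[k] <- radii[i]
    }
  }
  if (k == 0L) return(NULL)
  ii <- seq_len(k)
  data.frame(seg = seg_o[ii], surface = surf_o[ii], region = reg_o[ii],
             px = num[ii, 1L], py = num[ii, 2L], pz = num[ii, 3L],
             cx = num[ii, 4L], cy = num[ii, 5L], cz = num[ii, 6L],
             nx = num[ii, 7L], ny = num[ii, 8L], nz = num[ii, 9L],
             penetration = num[ii, 10L], vrx = num[ii, 11L],
             vry = num[ii, 12L], vrz = num[ii, 13L], radius = rad_o[ii],
             stringsAsFactors = FALSE)
}

#' Contact force from a penetration-stiffness curve with friction
#'
#' Normal magnitude from the loading branch (or the hysteretic unloading
#' branch when the penetration rate is negative); tangential force is
#' Coulomb friction opposing the relative tangential velocity,
#' regularized linearly below a slip-speed threshold.
#'
#' @param contact one row of [detect_contacts()] (list or data.frame row).
#' @param curve the [contact_curve()] for this surface region.
#' @param mu Coulomb friction coefficient.
#' @param v_eps slip-speed regularization threshold, m/s.
#' @return world force vector on the body (N) with attributes `normal_mag`
#'   and `tangential_mag`.
#' @export
contact_force <- function(contact, curve, mu, v_eps = 0.01) {
  n <- c(contact$nx, contact$ny, contact$nz)
  vr <- c(contact$vrx, contact$vry, contact$vrz)
  pen_rate <- -sum(vr * n)
  Fl <- curve_force(curve, contact$penetration)
  Fn <- if (pen_rate >= 0) Fl else curve$hysteresis * Fl
  vt <- vr - sum(vr * n) * n
  st <- sqrt(sum(vt^2))
  ft <- if (st > v_eps) -mu * Fn * vt / st else -mu * Fn * vt / v_eps
  out <- Fn * n + ft
  attr(out, "normal_mag") <- Fn
  attr(out, "tangential_mag") <- sqrt(sum(ft^2))
  out
}
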