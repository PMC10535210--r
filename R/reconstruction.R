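## Two-stage reconstruction of a car collision with a running pedestrian:
## stage 1 generates the pre-impact running state (gait + joint planning +
## collision-moment pose), stage 2 advances the articulated pedestrian
## through vehicle and ground contact to rest and evaluates injury and
## throw/rest metrics.  A photogrammetric helper converts video-frame
## displacements into impact speeds.

#' Vehicle speed from photogrammetric frame measurements
#'
#' @param distance displacement between the two frames, m.
#' @param frame_a,frame_b frame indices (`frame_b > frame_a`).
#' @param fps video frame rate, 1/s.
#' @return list with `speed` (m/s) and `band`, the +/-10 % measurement
#'   uncertainty interval customary for video photogrammetry.
#' @export
speed_from_frames <- function(distance, frame_a, frame_b, fps) {
  check_number(distance, "distance", 0)
  check_number(fps, "fps", 0, strict_lower = TRUE)
  if (frame_b <= frame_a)
    stopf("invalid frame interval: frame_b (%s) must exceed frame_a (%s)",
          frame_b, frame_a)
  speed <- distance * fps / (frame_b - frame_a)
  list(speed = speed, band = c(0.9, 1.1) * speed)
}

#' Collision scenario definition
#'
#' @param stature,mass pedestrian anthropometry (m, kg).
#' @param ped_speed pedestrian target running speed, m/s.
#' @param ped_heading_deg pedestrian heading, deg (0 = +x).
#' @param vehicle a [sedan_profile()]/[vehicle_profile()] (with `speed`).
#' @param vehicle_speed vehicle speed, m/s (overrides `vehicle$speed`).
#' @param vehicle_angle_deg angle between the vehicle path and the normal
#'   of the pedestrian's crossing direction, deg (2.7 in the shipped
#'   case).
#' @param friction a [friction_spec()].
#' @param mode initial pedestrian motion: `"running_dynamic"` (full
#'   stage-1 gait), `"translating_static_pose"` (static posture, whole
#'   body translating at `ped_speed`) or `"static"` (static posture at
#'   rest).
#' @param impact_phase stride fraction struck at impact, or `"mid_stance"`
#'   (default, mid left-stance as in the reconstructed case).
#' @param dt collision integration step, s.
#' @param max_time simulation horizon, s.
#' @param t_lead free running time before the bumper reaches the
#'   pedestrian, s.
#' @param rest_ke_threshold,rest_window rest detection: whole-body kinetic
#'   energy below the threshold (J) sustained for the window (s).
#' @return object of class `"scenario"`.
#' @export
scenario <- function(stature = 1.74, mass = 68, ped_speed = 4.5,
                     ped_heading_deg = 0, vehicle = sedan_profile(),
                     vehicle_speed = NULL, vehicle_angle_deg = 2.7,
                     friction = friction_spec(),
                     mode = c("running_dynamic", "translating_static_pose",
                              "static"),
                     impact_phase = "mid_stance", dt = 1e-4,
                     max_time = 3, t_lead = 0.06,
                     rest_ke_threshold = 1, rest_window = 0.2) {
  mode <- match.arg(mode)
  check_number(ped_speed, "ped_speed", 0)
  vehicle_speed <- vehicle_speed %||% vehicle$speed %||% 0
  check_number(vehicle_speed, "vehicle_speed", 0)
  structure(list(stature = stature, mass = mass, ped_speed = ped_speed,
                 ped_heading_deg = ped_heading_deg, vehicle = vehicle,
                 vehicle_speed = vehicle_speed,
                 vehicle_angle_deg = vehicle_angle_deg,
                 friction = friction, mode = mode,
                 impact_phase = impact_phase, dt = dt,
                 max_time = max_time, t_lead = t_lead,
                 rest_ke_threshold = rest_ke_threshold,
                 rest_window = rest_window),
            class = "scenario")
}

## standing pose (all joints neutral)
standing_pose <- function() {
  structure(list(joints = NULL, body_parts = NULL, timestamp = 0),
            trunk_pitch = 0, class = "pose")
}

#' Stage 1: pre-impact running state
#'
#' For the `running_dynamic` mode, finds the periodic gait at the target
#' speed, builds the joint trajectory and samples the collision-moment
#' pose at the configured impact phase. The other two modes return the
#' static posture with or without a whole-body translation velocity.
#'
#' @param scn a [scenario()].
#' @return list of class `"stage1_result"` with `pose`, `com_velocity`
#'   (3-vector, world), and for the dynamic mode `gait` and `trajectory`.
#' @export
run_stage1 <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  if (scn$mode == "static") {
    return(structure(list(pose = standing_pose(),
                          com_velocity = c(0, 0, 0), gait = NULL,
                          trajectory = NULL), class = "stage1_result"))
  }
  if (scn$mode == "translating_static_pose") {
    h <- scn$ped_heading_deg * pi / 180
    return(structure(list(
      pose = standing_pose(),
      com_velocity = scn$ped_speed * c(cos(h), sin(h), 0),
      gait = NULL, trajectory = NULL), class = "stage1_result"))
  }
  params <- slip_params(mass = scn$mass, stature = scn$stature)
  gait <- slip_gait(params, scn$ped_speed)
  topo <- skeleton_topology(scn$stature)
  model <- pedestrian_model(scn$stature, scn$mass, topo)
  traj <- build_joint_trajectory(gait, topo, model)
  t_st <- gait$stance$time[nrow(gait$stance)] - gait$stance$time[1L]
  t_imp <- if (identical(scn$impact_phase, "mid_stance")) 0.5 * t_st
           else scn$impact_phase * traj$stride_period
  pose <- sample_pose(traj, t_imp)
  cv <- attr(pose, "com_velocity")
  h <- scn$ped_heading_deg * pi / 180
  ## horizontal speed: the gait's mean forward speed (the commanded
  ## running speed) rather than the instantaneous within-cycle
  ## fluctuation; vertical from the sampled state
  vh <- gait$mean_forward_speed
  com_velocity <- c(vh * cos(h), vh * sin(h), cv[2L])
  structure(list(pose = pose, com_velocity = com_velocity, gait = gait,
                 trajectory = traj), class = "stage1_result")
}

## vehicle state (prescribed motion) at time t
vehicle_state_at <- function(setup, t) {
  list(position = setup$pos0 + setup$dir * setup$speed * t,
       heading = setup$heading,
       velocity = c(setup$dir * setup$speed, 0))
}

#' Stage 2: collision simulation through rest
#'
#' Initialises the articulated pedestrian from the stage-1 pose, aims the
#' prescribed-motion vehicle so its bumper reaches the pedestrian after
#' `t_lead`, and advances the coupled dynamics through vehicle and ground
#' contact until the whole-body kinetic energy stays below the rest
#' threshold for the configured window (or the horizon is reached, in
#' which case the result is flagged partial).
#'
#' @param scn a [scenario()].
#' @param stage1 a `"stage1_result"` (from [run_stage1()]).
#' @param record_every store kinematic samples every this many steps.
#' @return object of class `"pedrecon_reconstruction"`: event log,
#'   trajectory samples, throw/slide/rest metrics and an
#'   [assess_injury()] report.
#' @export
run_stage2 <- function(scn, stage1, record_every = 5L) {
  stopifnot(inherits(scn, "scenario"))
  ped <- pedestrian_model(scn$stature, scn$mass)
  model <- mb_model(ped)
  h <- scn$ped_heading_deg * pi / 180
  st <- apply_pose(model, stage1$pose, com_velocity = stage1$com_velocity,
                   heading = h)
  ## vehicle aimed at the pedestrian position after t_lead
  com0 <- mb_com(model, st$q)$com
  psi <- (-90 + scn$vehicle_angle_deg) * pi / 180 + h
  dirv <- c(cos(psi), sin(psi))
  target <- com0[1:2] + stage1$com_velocity[1:2] * scn$t_lead
  ## a stationary vehicle is parked with a standoff instead of on the
  ## aim point
  standoff <- if (scn$vehicle_speed > 0) 0 else 3
  pos0 <- target - dirv * (scn$vehicle_speed * scn$t_lead + standoff)
  setup <- list(pos0 = pos0, dir = dirv, speed = scn$vehicle_speed,
                heading = psi)
  mu_pg <- scn$friction$mu_ped_ground
  mu_cp <- scn$friction$mu_car_ped
  gcurve <- ground_curve()
  dt <- scn$dt
  n_max <- ceiling(scn$max_time / dt)
  seg_mass <- stats::setNames(ped$segments$mass, ped$segments$name)
  ## effective mass for the friction-impulse cap: the smaller of the
  ## segment mass and its rotational equivalent (min principal inertia
  ## over squared contact lever arm), so rubbing contacts cannot spin a
  ## light segment up within a step
  seg_meff <- vapply(ped$segments$name, function(s) {
    k <- which(ped$segments$name == s)
    lever <- 0.5 * sqrt(sum((ped$capsule_p1[k, ] - ped$capsule_p0[k, ])^2)) +
      ped$capsule_r[k]
    min(seg_mass[[s]], min(diag(ped$inertia[[k]])) / lever^2)
  }, 0)
  ## logs
  ev_time <- numeric(0); ev_seg <- character(0)
  ev_surface <- character(0); ev_region <- character(0)
  seen <- character(0)
  peak_force <- list()
  nrec <- ceiling(n_max / record_every) + 2L
  rec <- list(t = numeric(nrec), com = matrix(0, nrec, 3L),
              head = matrix(0, nrec, 3L), ke = numeric(nrec),
              max_z = numeric(nrec), ground = logical(nrec),
              vehicle = logical(nrec))
  irec <- 0L
  vh <- matrix(0, n_max + 1L, 3L)   # head COM velocity per step
  vc <- matrix(0, n_max + 1L, 3L)   # chest (upper trunk) COM velocity
  tv <- numeric(n_max + 1L)
  rest_since <- NA_real_
  partial <- TRUE
  env <- new.env()
  loads <- function(t, q, qd) {
    kin <- mb_seg_kin(model, q, qd)
    env$kin <- kin
    pts <- capsule_points(model, q, qd, kin = kin)
    vs <- vehicle_state_at(setup, t)
    ct <- detect_contacts_pts(pts, scn$vehicle, vs, 0)
    env$contacts <- ct
    f_ext <- list()
    modal <- rep(0, nrow(model$modes))
    if (!is.null(ct)) for (i in seq_len(nrow(ct))) {
      row <- list(seg = ct$seg[i], surface = ct$surface[i],
                  region = ct$region[i], nx = ct$nx[i], ny = ct$ny[i],
                  nz = ct$nz[i], vrx = ct$vrx[i], vry = ct$vry[i],
                  vrz = ct$vrz[i], penetration = ct$penetration[i])
      if (row$surface == "ground") {
        curve <- gcurve; mu <- mu_pg
      } else {
        curve <- scn$vehicle$curves[[row$region]]; mu <- mu_cp
      }
      f <- contact_force(row, curve, mu)
      ## cap the regularized friction impulse for step stability
      fn <- attr(f, "normal_mag")
      n <- c(row$nx, row$ny, row$nz)
      vt <- c(row$vrx, row$vry, row$vrz)
      vt <- vt - sum(vt * n) * n
      stv <- sqrt(sum(vt^2))
      ftmax <- seg_meff[[row$seg]] * stv / dt
      ftv <- f - fn * n
      ftm <- sqrt(sum(ftv^2))
      if (ftm > ftmax && ftm > 0) f <- fn * n + ftv * (ftmax / ftm)
      p <- c(ct$cx[i], ct$cy[i], ct$cz[i])
      w <- c(cross3(p, f), f)
      f_ext[[row$seg]] <- (f_ext[[row$seg]] %||% numeric(6L)) + w
      key <- paste(row$seg, row$surface, row$region, sep = "|")
      pk <- peak_force[[key]]
      if (is.null(pk)) {
        peak_force[[key]] <<- fn
        seen <<- c(seen, key)
        ev_time <<- c(ev_time, t); ev_seg <<- c(ev_seg, row$seg)
        ev_surface <<- c(ev_surface, row$surface)
        ev_region <<- c(ev_region, row$region)
      } else if (fn > pk) peak_force[[key]] <<- fn
      mi <- which(model$modes$host == row$seg)
      if (length(mi)) modal[mi] <- modal[mi] + fn
    }
    list(f_ext = f_ext, modal = modal)
  }
  step <- 0L
  while (step < n_max) {
    st <- mb_step(st, model, loads = loads, dt = dt,
                  method = "semi_implicit")
    step <- step + 1L
    kin <- env$kin
    tv[step] <- st$t
    vh[step, ] <- kin$head$v_com
    vc[step, ] <- kin$upper_trunk$v_com
    ke <- 0
    for (s in names(kin)) ke <- ke + 0.5 * kin[[s]]$mass *
      sum(kin[[s]]$v_com^2)
    if (step %% record_every == 1L || record_every == 1L) {
      irec <- irec + 1L
      M <- sum(seg_mass)
      cm <- Reduce(`+`, lapply(kin, function(k) k$mass * k$com)) / M
      rec$t[irec] <- st$t
      rec$com[irec, ] <- cm
      rec$head[irec, ] <- kin$head$com
      rec$ke[irec] <- ke
      rec$max_z[irec] <- max(vapply(kin, function(k) k$com[3L], 0))
      ctc <- env$contacts
      rec$ground[irec] <- !is.null(ctc) && any(ctc$surface == "ground")
      rec$vehicle[irec] <- !is.null(ctc) && any(ctc$surface == "vehicle")
    }
    if (ke < scn$rest_ke_threshold) {
      if (is.na(rest_since)) rest_since <- st$t
      if (st$t - rest_since >= scn$rest_window) { partial <- FALSE; break }
    } else rest_since <- NA_real_
  }
  nst <- step
  rec$t <- rec$t[seq_len(irec)]; rec$com <- rec$com[seq_len(irec), , drop = FALSE]
  rec$head <- rec$head[seq_len(irec), , drop = FALSE]
  rec$ke <- rec$ke[seq_len(irec)]; rec$max_z <- rec$max_z[seq_len(irec)]
  rec$ground <- rec$ground[seq_len(irec)]
  rec$vehicle <- rec$vehicle[seq_len(irec)]
  events <- data.frame(time = ev_time, seg = ev_seg, surface = ev_surface,
                       region = ev_region, stringsAsFactors = FALSE)
  events <- events[order(events$time), , drop = FALSE]
  ## proper acceleration traces in g (finite difference of COM velocity,
  ## minus gravity so free flight reads 0 g and rest reads 1 g)
  acc_of <- function(vmat) {
    n <- nst
    dv <- (vmat[2:n, , drop = FALSE] - vmat[1:(n - 1L), , drop = FALSE]) / dt
    dv[, 3L] <- dv[, 3L] + GRAV
    accel_trace(tv[2:n], sqrt(rowSums(dv^2)) / GRAV)
  }
  head_trace <- acc_of(vh)
  chest_trace <- acc_of(vc)
  hic_res <- hic(head_trace)
  chest_val <- chest_3ms(chest_trace)
  ## long-bone stress proxy from peak vehicle-contact force on the limbs
  bones <- bone_geometry(scn$stature)
  pf <- function(segs) {
    keys <- names(peak_force)
    m <- 0
    for (k in keys) {
      parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
      if (parts[1L] %in% segs && parts[2L] == "vehicle")
        m <- max(m, peak_force[[k]])
    }
    m
  }
  tibia_F <- pf(c("calf_l", "calf_r"))
  femur_F <- pf(c("thigh_l", "thigh_r"))
  stresses <- c(
    tibia = long_bone_stress(tibia_F, bones$tibia$length,
                             bones$tibia$r_outer, bones$tibia$r_inner),
    femur = long_bone_stress(femur_F, bones$femur$length,
                             bones$femur$r_outer, bones$femur$r_inner))
  injury <- assess_injury(hic_res, chest_val, stresses)
  ## throw / slide / rest metrics
  veh_ev <- events[events$surface == "vehicle", , drop = FALSE]
  t_first <- if (nrow(veh_ev)) min(veh_ev$time) else NA_real_
  first_cp <- if (nrow(veh_ev)) {
    i <- which.min(veh_ev$time)
    NULL
  } else NULL
  impact_xy <- if (!is.na(t_first)) {
    k <- which.min(abs(rec$t - t_first))
    rec$com[k, 1:2]
  } else c(NA_real_, NA_real_)
  ## airborne window: after last vehicle contact sample, before the first
  ## subsequent sustained ground contact
  max_air <- NA_real_; t_land <- NA_real_
  if (!is.na(t_first)) {
    iv <- which(rec$vehicle)
    i_sep <- if (length(iv)) max(iv) else 1L
    ig <- which(rec$ground & seq_along(rec$t) > i_sep)
    airborne <- if (length(ig)) seq(i_sep, ig[1L]) else
      seq(i_sep, length(rec$t))
    max_air <- if (length(airborne)) max(rec$max_z[airborne]) else NA_real_
    if (length(ig)) t_land <- rec$t[ig[1L]]
    if (!length(ig)) {
      ## vehicle contact and ground contact overlap (low-speed cases)
      ig2 <- which(rec$ground & rec$t > t_first)
      if (length(ig2)) t_land <- rec$t[ig2[1L]]
    }
  }
  com_rest <- rec$com[irec, ]
  slide <- if (!is.na(t_land)) {
    k <- which.min(abs(rec$t - t_land))
    sqrt(sum((com_rest[1:2] - rec$com[k, 1:2])^2))
  } else 0
  thrown <- if (!is.na(t_first))
    sqrt(sum((rec$head[irec, 1:2] - impact_xy)^2)) else NA_real_
  heading_vec <- rec$head[irec, 1:2] - com_rest[1:2]
  body_heading <- atan2(heading_vec[2L], heading_vec[1L]) * 180 / pi
  structure(list(
    scenario = scn, events = events, samples = rec,
    head_trace = head_trace, chest_trace = chest_trace,
    injury = injury,
    metrics = list(
      t_first_vehicle_contact = t_first,
      max_airborne_height = max_air,
      t_landing = t_land,
      slide_distance = slide,
      thrown_distance = thrown,
      rest_position = com_rest[1:2],
      body_heading_deg = body_heading,
      hic = hic_res$value, chest_3ms = chest_val,
      bone_stress = stresses,
      duration = st$t, partial = partial),
    final_state = st, model = model, vehicle_setup = setup),
    class = "pedrecon_reconstruction")
}

#' Full two-stage reconstruction
#'
#' @param scn a [scenario()].
#' @param ... passed to [run_stage2()].
#' @return a `"pedrecon_reconstruction"` (with the stage-1 result
#'   attached as `stage1`).
#' @export
reconstruct <- function(scn, ...) {
  s1 <- run_stage1(scn)
  res <- run_stage2(scn, s1, ...)
  res$stage1 <- s1
  res
}

#' @export
print.pedrecon_reconstruction <- function(x, ...) {
  m <- x$metrics
  cat("Pedestrian-vehicle collision reconstruction\n")
  cat(sprintf("  mode: %s | vehicle %.2f m/s | pedestrian %.2f m/s\n",
              x$scenario$mode, x$scenario$vehicle_speed,
              x$scenario$ped_speed))
  cat(sprintf("  simulated %.2f s%s; %d contact events\n", m$duration,
              if (m$partial) " (partial: horizon reached)" else "",
              nrow(x$events)))
  cat(sprintf("  HIC %.0f | chest 3 ms %.1f g | tibia %.1f MPa | femur %.1f MPa\n",
              m$hic, m$chest_3ms, m$bone_stress[["tibia"]],
              m$bone_stress[["femur"]]))
  cat(sprintf("  max airborne height %.2f m | slide %.2f m | thrown %.2f m\n",
              m$max_airborne_height, m$slide_distance, m$thrown_distance))
  cat(sprintf("  rest position (%.2f, %.2f) m, body heading %.1f deg\n",
              m$rest_position[1L], m$rest_position[2L],
              m$body_heading_deg))
  invisible(x)
}

#' @export
summary.pedrecon_reconstruction <- function(object, ...) {
  print(object)
  cat("\nFirst contact events:\n")
  print(utils::head(object$events, 10L), row.names = FALSE)
  invisible(object)
}

#' @export
plot.pedrecon_reconstruction <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$samples$com[, 1L], x$samples$com[, 3L], type = "l",
                 xlab = "x (m)", ylab = "z (m)", main = "COM trajectory")
  graphics::plot(x$head_trace$time, x$head_trace$accel, type = "l",
                 xlab = "time (s)", ylab = "head acceleration (g)",
                 main = "Head resultant")
  invisible(x)
}

#' Compare reconstruction cases against a baseline
#'
#' Relative errors `|x_k - x_1| / x_1` of the injury metrics and the
#' rest-position offset of each case against the first (baseline) case,
#' in the layout of a multi-case comparison table.
#'
#' @param results list of `"pedrecon_reconstruction"` (>= 2); the first is
#'   the baseline.
#' @param labels case labels; default `case1, case2, ...`.
#' @return data.frame with one row per non-baseline case and columns
#'   `comparison`, `HIC_pct`, `chest_3ms_pct`, `lower_limb_stress_pct`,
#'   `rest_position_offset_m`. Undefined ratios (zero baseline) are `NA`.
#' @export
compare_cases <- function(results, labels = NULL) {
  if (length(results) < 2L) stopf("need at least two cases to compare")
  labels <- labels %||% paste0("case", seq_along(results))
  met <- function(r) c(HIC = r$metrics$hic,
                       chest = r$metrics$chest_3ms,
                       stress = max(r$metrics$bone_stress))
  base <- met(results[[1L]])
  rows <- NULL
  for (k in 2:length(results)) {
    mk <- met(results[[k]])
    rel <- ifelse(base == 0, NA_real_, abs(mk - base) / base * 100)
    off <- sqrt(sum((results[[k]]$metrics$rest_position -
                       results[[1L]]$metrics$rest_position)^2))
    rows <- rbind(rows, data.frame(
      comparison = sprintf("%s with %s", labels[k], labels[1L]),
      HIC_pct = rel[["HIC"]], chest_3ms_pct = rel[["chest"]],
      lower_limb_stress_pct = rel[["stress"]],
      rest_position_offset_m = off, stringsAsFactors = FALSE))
  }
  rows
}
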