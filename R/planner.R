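## Joint-space planning of the running motion.
##
## The centroid gait fixes the pelvis path; cubic-spline swing-foot arcs
## and planar two-link inverse kinematics produce the leg joint series,
## the arms swing anti-phase with the ipsilateral leg, and the trunk keeps
## a small constant forward lean.  Sagittal angles are measured about the
## +y (left) axis, so a limb channel value q places the limb direction at
## (-sin q, -cos q) in the (x, z) plane: positive q swings the limb
## backward, knee flexion is positive.

limb_dir <- function(theta) cbind(-sin(theta), -cos(theta))

#' Planar two-link leg inverse kinematics
#'
#' Returns the knee-forward solution for a hip--knee--ankle chain in the
#' sagittal plane.
#'
#' @param hip hip position `c(x, z)`, m.
#' @param foot ankle target `c(x, z)`, m.
#' @param thigh_len,calf_len segment lengths, m.
#' @param trunk_pitch pelvis pitch about +y, rad; the returned hip channel
#'   is relative to the pelvis.
#' @return named numeric `c(hip_R2, knee_R1)` (rad); attribute
#'   `near_singular` is `TRUE` when the target is at full extension.
#' @export
solve_leg_ik <- function(hip, foot, thigh_len, calf_len, trunk_pitch = 0) {
  d <- foot - hip
  D <- sqrt(sum(d^2))
  reach <- thigh_len + calf_len
  if (D > reach + 1e-12)
    stopf("IK target out of reach: distance %.4f m > leg length %.4f m",
          D, reach)
  if (D < abs(thigh_len - calf_len))
    stopf("IK target too close: distance %.4f m", D)
  theta_d <- atan2(-d[1L], -d[2L])
  cb <- (thigh_len^2 + D^2 - calf_len^2) / (2 * thigh_len * D)
  beta <- acos(min(1, max(-1, cb)))
  cphi <- (thigh_len^2 + calf_len^2 - D^2) / (2 * thigh_len * calf_len)
  knee <- pi - acos(min(1, max(-1, cphi)))
  theta_thigh <- theta_d - beta
  out <- c(hip_R2 = theta_thigh - trunk_pitch, knee_R1 = knee)
  attr(out, "near_singular") <- D > reach - 1e-9
  out
}

#' Forward kinematics of the planar leg chain
#'
#' @param hip hip position `c(x, z)`.
#' @param hip_R2,knee_R1 joint channels as returned by [solve_leg_ik()].
#' @param thigh_len,calf_len segment lengths, m.
#' @param trunk_pitch pelvis pitch, rad.
#' @return list with `knee` and `ankle` positions `c(x, z)`.
#' @export
leg_fk <- function(hip, hip_R2, knee_R1, thigh_len, calf_len,
                   trunk_pitch = 0) {
  th <- trunk_pitch + hip_R2
  tc <- th + knee_R1
  knee <- hip + thigh_len * c(-sin(th), -cos(th))
  ankle <- knee + calf_len * c(-sin(tc), -cos(tc))
  list(knee = knee, ankle = ankle)
}

#' Plan stance and swing foot (ankle) trajectories
#'
#' The stance ankle stays fixed over its foothold; the swing ankle follows
#' clamped cubic-spline arcs (zero velocity at lift-off and touchdown)
#' between consecutive footholds, passing through a mid-swing knot exactly
#' `swing_clearance` above the stance height.
#'
#' @param gait a [slip_gait()] object.
#' @param swing_clearance mid-swing ankle height above its stance height, m.
#' @param n_strides planning horizon in strides (1 stride = 2 steps).
#' @param ankle_height ankle height above the ground during stance, m.
#' @return object of class `"foot_plan"`: per-leg piecewise description
#'   with an evaluator `foot_state(plan, leg, t)` giving position and
#'   velocity.
#' @export
plan_foot_trajectory <- function(gait, swing_clearance = 0.10,
                                 n_strides = 2L, ankle_height = 0) {
  stopifnot(inherits(gait, "slip_gait"))
  check_number(swing_clearance, "swing_clearance", 0, strict_lower = TRUE)
  if (swing_clearance >= gait$params$q_r0)
    stopf("swing clearance %.3f m exceeds the leg length %.3f m",
          swing_clearance, gait$params$q_r0)
  P <- gait$step_period
  t_st <- gait$stance$time[nrow(gait$stance)] - gait$stance$time[1L]
  SL <- gait$step_length
  fh0 <- attr(gait$stance, "foothold")[1L]
  ## touchdown j at time j*P with foothold fh0 + j*SL; even j = left leg
  ## (j < 0 covers swings already in progress at t = 0)
  jj <- seq(-2L, 2L * n_strides + 1L)
  swings <- stats::setNames(vector("list", length(jj)), as.character(jj))
  for (j in jj) {
    t_lo <- j * P + t_st
    t_td <- (j + 2L) * P
    x0 <- fh0 + j * SL; x1 <- fh0 + (j + 2L) * SL
    tm <- (t_lo + t_td) / 2
    ## forward progress stays near-linear mid-swing (the ankle must not
    ## lag the advancing hip beyond leg reach) while still departing and
    ## landing with zero velocity
    tau <- c(0, 0.15, 0.5, 0.85, 1)
    prog <- c(0, 0.12, 0.5, 0.88, 1)
    sx <- clamped_spline(t_lo + tau * (t_td - t_lo), x0 + prog * (x1 - x0),
                         deriv_left = 0, deriv_right = 0)
    sz <- clamped_spline(c(t_lo, tm, t_td),
                         ankle_height + c(0, swing_clearance, 0),
                         deriv_left = 0, deriv_right = 0)
    swings[[as.character(j)]] <- list(j = j, t_lo = t_lo, t_td = t_td,
                                      sx = sx, sz = sz)
  }
  structure(list(P = P, t_st = t_st, SL = SL, fh0 = fh0,
                 ankle_height = ankle_height,
                 clearance = swing_clearance, swings = swings,
                 horizon = (2L * n_strides) * P),
            class = "foot_plan")
}

#' Evaluate a foot plan
#'
#' @param plan a [plan_foot_trajectory()] object.
#' @param leg `"left"` or `"right"`.
#' @param t times, s (within the planning horizon).
#' @return data.frame with `x`, `z`, `vx`, `vz` and logical `stance`.
#' @export
foot_state <- function(plan, leg, t) {
  leg <- match.arg(leg, c("left", "right"))
  par0 <- if (leg == "left") 0L else 1L
  out <- data.frame(x = numeric(length(t)), z = 0, vx = 0, vz = 0,
                    stance = FALSE)
  for (i in seq_along(t)) {
    ## most recent touchdown of this leg at or before t
    j <- par0 + 2L * floor((t[i] - par0 * plan$P) / (2 * plan$P))
    t_td <- j * plan$P
    if (t[i] >= t_td - 1e-12 && t[i] <= t_td + plan$t_st + 1e-12) { # stance
      out$x[i] <- plan$fh0 + j * plan$SL
      out$z[i] <- plan$ankle_height
      out$stance[i] <- TRUE
    } else {                                   # swing spline j
      sw <- plan$swings[[as.character(j)]]
      if (is.null(sw)) stopf("time %.3f outside foot-plan horizon", t[i])
      out$x[i] <- spline_eval(sw$sx, t[i])
      out$z[i] <- spline_eval(sw$sz, t[i])
      out$vx[i] <- spline_eval(sw$sx, t[i], 1L)
      out$vz[i] <- spline_eval(sw$sz, t[i], 1L)
    }
  }
  out
}

#' Plan the arm swing
#'
#' Shoulders oscillate sinusoid-like (spline through sinusoid knots)
#' anti-phase with the ipsilateral leg, one cycle per stride; elbow angles
#' are held constant (the elbow degree of freedom is ignored during the
#' running phase).
#'
#' @param gait a [slip_gait()] object.
#' @param amplitude shoulder swing amplitude, rad.
#' @param elbow_flexion constant elbow R2 value, rad.
#' @param n_strides planning horizon in strides.
#' @return object of class `"arm_plan"` with left/right shoulder splines
#'   and constant elbow values.
#' @export
plan_arm_swing <- function(gait, amplitude = 0.4, elbow_flexion = -1.45,
                           n_strides = 2L) {
  stopifnot(inherits(gait, "slip_gait"))
  check_number(amplitude, "amplitude", 0)
  T <- 2 * gait$step_period
  tt <- seq(0, n_strides * T, by = T / 8)
  ## left leg touches down at t = 0 (thigh forward) -> left shoulder back
  yl <- amplitude * cos(2 * pi * tt / T)
  sl <- clamped_spline(tt, yl, deriv_left = 0,
                       deriv_right = -amplitude * 2 * pi / T *
                         sin(2 * pi * tt[length(tt)] / T))
  sr <- clamped_spline(tt, -yl, deriv_left = 0,
                       deriv_right = amplitude * 2 * pi / T *
                         sin(2 * pi * tt[length(tt)] / T))
  structure(list(T = T, amplitude = amplitude, shoulder_l = sl,
                 shoulder_r = sr, elbow = elbow_flexion,
                 horizon = n_strides * T),
            class = "arm_plan")
}

## 2-D sagittal whole-body COM given channel values at one time
## (masses from the model; lateral offsets cancel by symmetry)
planner_com <- function(model, pelvis, pitch, qs) {
  topo <- model$topology
  seg <- model$segments
  L <- function(s) seg$length[seg$name == s]
  cf <- function(s) seg$com_frac[seg$name == s]
  m <- function(s) seg$mass[seg$name == s]
  pos <- list()
  dir2 <- function(th) c(-sin(th), -cos(th))
  up2 <- function(th) c(sin(th), cos(th))
  ## trunk chain (origins)
  pos$pelvis <- pelvis
  pos$lower_trunk <- pelvis + L("pelvis") * up2(pitch)
  pos$upper_trunk <- pos$lower_trunk + L("lower_trunk") * up2(pitch)
  pos$neck <- pos$upper_trunk + L("upper_trunk") * up2(pitch)
  pos$head <- pos$neck + L("neck") * up2(pitch)
  sh <- pos$upper_trunk + 0.9 * L("upper_trunk") * up2(pitch)
  com <- c(0, 0); M <- 0
  add <- function(com, M, name, origin, theta, upward = FALSE) {
    len <- L(name); f <- cf(name)
    cvec <- if (upward) origin + f * len * up2(theta)
            else origin + f * len * dir2(theta)
    list(com = com + m(name) * cvec, M = M + m(name))
  }
  for (s in c("pelvis", "lower_trunk", "upper_trunk", "neck", "head")) {
    r <- add(com, M, s, pos[[s]], pitch, upward = TRUE)
    com <- r$com; M <- r$M
  }
  for (side in c("l", "r")) {
    S <- if (side == "l") "L" else "R"
    th_t <- pitch + qs[[paste0("Hip", S, ".R2")]]
    th_c <- th_t + qs[[paste0("Knee", S, ".R1")]]
    hip <- pelvis
    r <- add(com, M, paste0("thigh_", side), hip, th_t)
    com <- r$com; M <- r$M
    knee <- hip + L(paste0("thigh_", side)) * dir2(th_t)
    r <- add(com, M, paste0("calf_", side), knee, th_c)
    com <- r$com; M <- r$M
    ankle <- knee + L(paste0("calf_", side)) * dir2(th_c)
    th_f <- th_c + qs[[paste0("Tibia", S, ".R1")]]
    ## foot COM: forward of the ankle, below by the ankle height
    fc <- ankle + 0.25 * L(paste0("foot_", side)) *
      c(cos(th_f), -sin(th_f)) - c(0, 0.7 * topo$ankle_height)
    com <- com + m(paste0("foot_", side)) * fc
    M <- M + m(paste0("foot_", side))
    th_ua <- pitch + qs[[paste0("Shoulder", S, ".R1")]]
    th_la <- th_ua + qs[[paste0("Elbow", S, ".R2")]]
    r <- add(com, M, paste0("upper_arm_", side), sh, th_ua)
    com <- r$com; M <- r$M
    elb <- sh + L(paste0("upper_arm_", side)) * dir2(th_ua)
    r <- add(com, M, paste0("lower_arm_", side), elb, th_la)
    com <- r$com; M <- r$M
  }
  com / M
}

#' Build the whole-body joint trajectory of the running motion
#'
#' Assembles swing-foot splines, leg inverse kinematics, arm swing and a
#' constant trunk pitch into per-joint angle series over one stride, then
#' interpolates every channel with a C2 cubic spline whose analytic
#' derivatives provide the angular velocities and accelerations. When a
#' [pedestrian_model()] is supplied, the pelvis is positioned so the
#' posed whole-body centre of mass tracks the virtual-leg centroid.
#'
#' @param gait a [slip_gait()] object.
#' @param topology a [skeleton_topology()].
#' @param model optional [pedestrian_model()] for COM-consistent pelvis
#'   placement (recommended).
#' @param n_grid samples per stride for the channel splines.
#' @param trunk_pitch constant forward lean of the trunk, rad.
#' @param swing_clearance,arm_amplitude,elbow_flexion,arm_adduction
#'   planner parameters (clearance m; angles rad).
#' @return object of class `"joint_trajectory"`: time grid, channel
#'   splines (named `Joint.Rk`), pelvis position/pitch splines, and the
#'   underlying plans.
#' @export
build_joint_trajectory <- function(gait, topology, model = NULL,
                                   n_grid = 121L, trunk_pitch = 0.1,
                                   swing_clearance = 0.10,
                                   arm_amplitude = 0.4,
                                   elbow_flexion = -1.45,
                                   arm_adduction = 0.25) {
  stopifnot(inherits(gait, "slip_gait"),
            inherits(topology, "skeleton_topology"))
  T <- 2 * gait$step_period
  fp <- plan_foot_trajectory(gait, swing_clearance, n_strides = 2L,
                             ankle_height = topology$ankle_height)
  ap <- plan_arm_swing(gait, arm_amplitude, elbow_flexion, n_strides = 2L)
  tt <- seq(0, T, length.out = n_grid)
  com_tr <- compose_gait(gait, n_steps = 3L, dt_out = T / (8 * n_grid))
  com_x <- stats::approx(com_tr$time, com_tr$com_x, tt, rule = 2)$y
  com_z <- stats::approx(com_tr$time, com_tr$com_z, tt, rule = 2)$y
  ## initial pelvis guess: centroid shifted down by the standing COM-to-hip
  ## offset (refined against the posed model below)
  h_off <- if (is.null(model)) 0.045 * topology$stature else {
    st_com <- planner_com(model, c(0, topology$hip_height), 0,
      as.list(stats::setNames(rep(0, 12),
        c("HipL.R2", "HipR.R2", "KneeL.R1", "KneeR.R1", "TibiaL.R1",
          "TibiaR.R1", "ShoulderL.R1", "ShoulderR.R1", "ElbowL.R2",
          "ElbowR.R2", "LumbarLow-LumbarUp.R2", "NeckLow-NeckUp.R2"))))
    st_com[2L] - topology$hip_height
  }
  channels <- c("HipL.R2", "HipR.R2", "KneeL.R1", "KneeR.R1",
                "TibiaL.R1", "TibiaR.R1", "ShoulderL.R1", "ShoulderR.R1",
                "ShoulderL.R2", "ShoulderR.R2", "ElbowL.R2", "ElbowR.R2")
  Q <- matrix(0, n_grid, length(channels),
              dimnames = list(NULL, channels))
  pel <- matrix(0, n_grid, 2)
  footL <- foot_state(fp, "left", tt)
  footR <- foot_state(fp, "right", tt)
  for (i in seq_len(n_grid)) {
    pelvis <- c(com_x[i], com_z[i] - h_off)
    ik_at <- function(pelvis) {
      ikL <- solve_leg_ik(pelvis, c(footL$x[i], footL$z[i]),
                          topology$thigh_len, topology$calf_len,
                          trunk_pitch)
      ikR <- solve_leg_ik(pelvis, c(footR$x[i], footR$z[i]),
                          topology$thigh_len, topology$calf_len,
                          trunk_pitch)
      list(
        "HipL.R2" = ikL[["hip_R2"]], "HipR.R2" = ikR[["hip_R2"]],
        "KneeL.R1" = ikL[["knee_R1"]], "KneeR.R1" = ikR[["knee_R1"]],
        "TibiaL.R1" = -(trunk_pitch + ikL[["hip_R2"]] + ikL[["knee_R1"]]),
        "TibiaR.R1" = -(trunk_pitch + ikR[["hip_R2"]] + ikR[["knee_R1"]]),
        "ShoulderL.R1" = spline_eval(ap$shoulder_l, tt[i]),
        "ShoulderR.R1" = spline_eval(ap$shoulder_r, tt[i]),
        "ElbowL.R2" = elbow_flexion, "ElbowR.R2" = elbow_flexion)
    }
    qs <- ik_at(pelvis)
    if (!is.null(model)) {
      ## fixed-point correction: shift the pelvis so the posed whole-body
      ## COM matches the centroid target; re-solve IK after every shift so
      ## the stored (pelvis, angles) pair stays consistent
      for (iter in 1:5) {
        com_now <- planner_com(model, pelvis, trunk_pitch, qs)
        err <- c(com_x[i], com_z[i]) - com_now
        if (sqrt(sum(err^2)) < 1e-11) break
        pelvis <- pelvis + err
        qs <- ik_at(pelvis)
      }
    }
    pel[i, ] <- pelvis
    Q[i, "HipL.R2"] <- qs[["HipL.R2"]]; Q[i, "HipR.R2"] <- qs[["HipR.R2"]]
    Q[i, "KneeL.R1"] <- qs[["KneeL.R1"]]
    Q[i, "KneeR.R1"] <- qs[["KneeR.R1"]]
    Q[i, "TibiaL.R1"] <- qs[["TibiaL.R1"]]
    Q[i, "TibiaR.R1"] <- qs[["TibiaR.R1"]]
    Q[i, "ShoulderL.R1"] <- qs[["ShoulderL.R1"]]
    Q[i, "ShoulderR.R1"] <- qs[["ShoulderR.R1"]]
    ## slight adduction: running arm carry keeps the forearms close to
    ## the body rather than protruding laterally
    Q[i, "ShoulderL.R2"] <- -arm_adduction
    Q[i, "ShoulderR.R2"] <- arm_adduction
    Q[i, "ElbowL.R2"] <- elbow_flexion; Q[i, "ElbowR.R2"] <- elbow_flexion
  }
  splines <- lapply(colnames(Q), function(ch) clamped_spline(tt, Q[, ch]))
  names(splines) <- colnames(Q)
  pelvis_x <- clamped_spline(tt, pel[, 1L])
  pelvis_z <- clamped_spline(tt, pel[, 2L])
  structure(list(time = tt, channels = Q, splines = splines,
                 pelvis_x = pelvis_x, pelvis_z = pelvis_z,
                 trunk_pitch = trunk_pitch, stride_period = T,
                 gait = gait, topology = topology, model = model,
                 foot_plan = fp, arm_plan = ap,
                 elbow_flexion = elbow_flexion),
            class = "joint_trajectory")
}

#' @export
print.joint_trajectory <- function(x, ...) {
  cat(sprintf(
    "Running joint trajectory: stride %.4f s, %d channels, %d knots\n",
    x$stride_period, ncol(x$channels), length(x$time)))
  invisible(x)
}

#' @export
plot.joint_trajectory <- function(x, channels = c("HipL.R2", "KneeL.R1"),
                                  ...) {
  tt <- seq(0, x$stride_period, length.out = 200)
  vals <- sapply(channels, function(ch) spline_eval(x$splines[[ch]], tt))
  graphics::matplot(tt, vals, type = "l", lty = 1, xlab = "time (s)",
                    ylab = "angle (rad)", ...)
  graphics::legend("topright", channels, col = seq_along(channels),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Sample a collision-moment pose from a joint trajectory
#'
#' Angles come from spline evaluation and angular velocities from the
#' analytic spline derivative, packaged in the two-table layout of the
#' collision-moment pose file (per-joint R1/R2/R3 angles plus per-body-part
#' angular speeds).
#'
#' @param traj a [build_joint_trajectory()] object.
#' @param t sample time, s (within the trajectory span).
#' @return object of class `"pose"`: `joints` and `body_parts` data frames,
#'   `timestamp`, and attributes `com_velocity` (m/s) and `trunk_pitch`.
#' @export
sample_pose <- function(traj, t) {
  stopifnot(inherits(traj, "joint_trajectory"))
  if (t < 0 || t > traj$stride_period)
    stopf("t = %.4f s outside the trajectory span [0, %.4f]",
          t, traj$stride_period)
  ch <- function(nm) spline_eval(traj$splines[[nm]], t)
  dch <- function(nm) spline_eval(traj$splines[[nm]], t, 1L)
  joints <- data.frame(
    joint = c("HipL", "HipR", "KneeL", "KneeR", "TibiaL", "TibiaR",
              "ElbowL", "ElbowR", "LumbarLow-LumbarUp", "NeckLow-NeckUp",
              "ShoulderL", "ShoulderR"),
    R1_rad = c(NA, NA, ch("KneeL.R1"), ch("KneeR.R1"), ch("TibiaL.R1"),
               ch("TibiaR.R1"), NA, NA, NA, NA, ch("ShoulderL.R1"),
               ch("ShoulderR.R1")),
    R2_rad = c(ch("HipL.R2"), ch("HipR.R2"), NA, NA, NA, NA,
               ch("ElbowL.R2"), ch("ElbowR.R2"), 0, 0,
               ch("ShoulderL.R2"), ch("ShoulderR.R2")),
    R3_rad = NA_real_,
    stringsAsFactors = FALSE)
  ## absolute sagittal angular speeds of the body parts (trunk pitch is
  ## constant, so thigh rate = hip channel rate, calf = hip + knee, arms
  ## follow the shoulder since the elbow is frozen)
  body_parts <- data.frame(
    body_part = c("Lower left arm", "Upper left arm", "Lower right arm",
                  "Upper right arm", "Left thigh", "Left calf",
                  "Right thigh", "Right calf"),
    angular_velocity_rad_per_s = abs(c(
      dch("ShoulderL.R1"), dch("ShoulderL.R1"),
      dch("ShoulderR.R1"), dch("ShoulderR.R1"),
      dch("HipL.R2"), dch("HipL.R2") + dch("KneeL.R1"),
      dch("HipR.R2"), dch("HipR.R2") + dch("KneeR.R1"))),
    stringsAsFactors = FALSE)
  com_vel <- c(spline_eval(traj$pelvis_x, t, 1L),
               spline_eval(traj$pelvis_z, t, 1L))
  signed <- lapply(colnames(traj$channels), function(nm) dch(nm))
  names(signed) <- colnames(traj$channels)
  structure(list(joints = joints, body_parts = body_parts, timestamp = t),
            com_velocity = com_vel, trunk_pitch = traj$trunk_pitch,
            signed_rates = signed,
            class = "pose")
}

#' Sample a strip of equally spaced running postures
#'
#' @param traj a [build_joint_trajectory()] object.
#' @param n number of postures (default 10, one strip per stride).
#' @return list of `n` [sample_pose()] objects at equal phase fractions.
#' @export
pose_strip <- function(traj, n = 10L) {
  tt <- seq(0, traj$stride_period, length.out = n + 1L)[seq_len(n)]
  lapply(tt, function(t) sample_pose(traj, t))
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("Collision-moment pose at t = %.4f s\n", x$timestamp))
  print(x$joints, row.names = FALSE)
  print(x$body_parts, row.names = FALSE)
  invisible(x)
}

#' Write a pose to CSV (two-table layout)
#'
#' Rows with `record_type = "joint"` carry R1/R2/R3 angles (rad); rows
#' with `record_type = "body_part"` carry angular speeds (rad/s). Numbers
#' are written in R's default shortest representation so a read/write
#' round trip is byte-stable.
#'
#' @param pose a `"pose"` object.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_pose <- function(pose, path) {
  j <- pose$joints; b <- pose$body_parts
  chr <- function(x) ifelse(is.na(x), "", as.character(x))
  df <- data.frame(
    record_type = c(rep("joint", nrow(j)), rep("body_part", nrow(b))),
    name = c(j$joint, b$body_part),
    R1_rad = c(chr(j$R1_rad), rep("", nrow(b))),
    R2_rad = c(chr(j$R2_rad), rep("", nrow(b))),
    R3_rad = c(chr(j$R3_rad), rep("", nrow(b))),
    angular_velocity_rad_per_s = c(rep("", nrow(j)),
                                   chr(b$angular_velocity_rad_per_s)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a pose CSV written by [write_pose()]
#'
#' @param path file path.
#' @return a `"pose"` object (timestamp 0 unless stored).
#' @export
read_pose <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "" | x == "NA",
                                                        NA, x)))
  jj <- df[df$record_type == "joint", , drop = FALSE]
  bb <- df[df$record_type == "body_part", , drop = FALSE]
  joints <- data.frame(joint = jj$name, R1_rad = num(jj$R1_rad),
                       R2_rad = num(jj$R2_rad), R3_rad = num(jj$R3_rad),
                       stringsAsFactors = FALSE)
  body_parts <- data.frame(
    body_part = bb$name,
    angular_velocity_rad_per_s = num(bb$angular_velocity_rad_per_s),
    stringsAsFactors = FALSE)
  structure(list(joints = joints, body_parts = body_parts, timestamp = 0),
            class = "pose")
}

#' Export a joint trajectory as wide CSV
#'
#' One column per joint-angle channel (`<Joint>.<Rk>_rad`) plus pelvis
#' position columns, sampled on the trajectory knot grid.
#'
#' @param traj a `"joint_trajectory"`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time_s = traj$time,
                   pelvis_x_m = spline_eval(traj$pelvis_x, traj$time),
                   pelvis_z_m = spline_eval(traj$pelvis_z, traj$time))
  for (ch in colnames(traj$channels))
    df[[paste0(gsub("[.]", "_", ch), "_rad")]] <- traj$channels[, ch]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
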