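## Anthropometric scaling of the articulated pedestrian.
##
## Segment lengths are standard stature fractions and segment masses are
## standard body-mass fractions (Winter-style tables, trunk split into
## pelvis / abdomen / thorax); inertia comes from solid-primitive formulas
## (cylinders for limbs and trunk, sphere for the head).  All values are
## documented presets of this package, overridable via the returned
## structures.

## mass fraction, length fraction (of stature), COM position along the
## segment axis as a fraction of segment length from the proximal joint,
## and capsule radius as a fraction of stature
SEGMENT_TABLE <- data.frame(
  name = c("pelvis", "lower_trunk", "upper_trunk", "neck", "head",
           "upper_arm_l", "upper_arm_r", "lower_arm_l", "lower_arm_r",
           "thigh_l", "thigh_r", "calf_l", "calf_r", "foot_l", "foot_r"),
  mass_frac = c(0.142, 0.139, 0.216, 0.021, 0.060,
                0.028, 0.028, 0.022, 0.022,
                0.100, 0.100, 0.0465, 0.0465, 0.0145, 0.0145),
  len_frac = c(0.078, 0.081, 0.129, 0.052, 0.130,
               0.186, 0.186, 0.146, 0.146,
               0.245, 0.245, 0.246, 0.246, 0.152, 0.152),
  com_frac = c(0.5, 0.5, 0.5, 0.5, 0.45,
               0.436, 0.436, 0.43, 0.43,
               0.433, 0.433, 0.433, 0.433, 0.5, 0.5),
  rad_frac = c(0.068, 0.063, 0.072, 0.032, 0.0635,
               0.023, 0.023, 0.020, 0.020,
               0.040, 0.040, 0.026, 0.026, 0.023, 0.023),
  stringsAsFactors = FALSE)

HIP_HALFWIDTH_FRAC <- 0.052      # lateral hip-joint offset / stature
SHOULDER_HALFWIDTH_FRAC <- 0.1295
ANKLE_HEIGHT_FRAC <- 0.039       # foot sole below the ankle joint

#' Skeleton topology scaled to a stature
#'
#' Returns the kinematic tree used by both the joint planner and the
#' multibody model: 15 named segments with lengths derived from stature
#' and 14 joints (including every joint name of the collision-moment pose
#' table layout: HipL/R, KneeL/R, TibiaL/R, ElbowL/R, ShoulderL/R,
#' LumbarLow-LumbarUp, NeckLow-NeckUp) with their rotation axes
#' \eqn{\xi, \eta, \zeta} (body-fixed x, y, z) and channel names R1, R2,
#' R3. The world frame has +x the walking direction, +y left, +z up; limb
#' segments extend along -z in the neutral standing pose.
#'
#' @param stature pedestrian stature, m.
#' @return list of class `"skeleton_topology"` with `segments` (lengths,
#'   radii), `joints` (parent/child, origin in parent frame, DOF channels
#'   with axes, stiffness/damping/limits presets) and convenience lengths.
#' @export
skeleton_topology <- function(stature = 1.74) {
  check_number(stature, "stature", 1.4, 2.1)
  H <- stature
  seg <- SEGMENT_TABLE
  seg$length <- seg$len_frac * H
  seg$radius <- seg$rad_frac * H
  L <- function(s) seg$length[seg$name == s]
  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1)
  dof3 <- function() list(R1 = ex, R2 = ey, R3 = ez)
  ## physiological-order-of-magnitude passive stiffness (N m/rad) and
  ## damping (N m s/rad) presets; stops engage beyond the limits
  jdef <- function(name, parent, child, origin, dofs, k, c, lim) {
    list(name = name, parent = parent, child = child, origin = origin,
         dofs = dofs, stiffness = k, damping = c, limits = lim,
         stop_stiffness = 300)
  }
  hipw <- HIP_HALFWIDTH_FRAC * H
  shw <- SHOULDER_HALFWIDTH_FRAC * H
  joints <- list(
    jdef("PelvisLumbar", "pelvis", "lower_trunk",
         c(0, 0, L("pelvis")), dof3(), 200, 20, c(-1.2, 1.2)),
    jdef("LumbarLow-LumbarUp", "lower_trunk", "upper_trunk",
         c(0, 0, L("lower_trunk")), dof3(), 200, 20, c(-1.2, 1.2)),
    jdef("ThoraxNeck", "upper_trunk", "neck",
         c(0, 0, L("upper_trunk")), dof3(), 30, 8, c(-1.2, 1.2)),
    jdef("NeckLow-NeckUp", "neck", "head",
         c(0, 0, L("neck")), dof3(), 30, 8, c(-1.2, 1.2)),
    jdef("ShoulderL", "upper_trunk", "upper_arm_l",
         c(0, shw, 0.9 * L("upper_trunk")),
         list(R1 = ey, R2 = ex, R3 = ez), 10, 3, c(-3.2, 3.2)),
    jdef("ShoulderR", "upper_trunk", "upper_arm_r",
         c(0, -shw, 0.9 * L("upper_trunk")),
         list(R1 = ey, R2 = ex, R3 = ez), 10, 3, c(-3.2, 3.2)),
    jdef("ElbowL", "upper_arm_l", "lower_arm_l",
         c(0, 0, -L("upper_arm_l")),
         list(R1 = ex, R2 = ey), 8, 2, c(-2.8, 2.8)),
    jdef("ElbowR", "upper_arm_r", "lower_arm_r",
         c(0, 0, -L("upper_arm_r")),
         list(R1 = ex, R2 = ey), 8, 2, c(-2.8, 2.8)),
    jdef("HipL", "pelvis", "thigh_l",
         c(0, hipw, 0), list(R1 = ex, R2 = ey, R3 = ez),
         60, 8, c(-2.2, 2.2)),
    jdef("HipR", "pelvis", "thigh_r",
         c(0, -hipw, 0), list(R1 = ex, R2 = ey, R3 = ez),
         60, 8, c(-2.2, 2.2)),
    jdef("KneeL", "thigh_l", "calf_l",
         c(0, 0, -L("thigh_l")), list(R1 = ey), 30, 4, c(-0.05, 2.6)),
    jdef("KneeR", "thigh_r", "calf_r",
         c(0, 0, -L("thigh_r")), list(R1 = ey), 30, 4, c(-0.05, 2.6)),
    jdef("TibiaL", "calf_l", "foot_l",
         c(0, 0, -L("calf_l")), list(R1 = ey, R2 = ex), 30, 3, c(-1, 1)),
    jdef("TibiaR", "calf_r", "foot_r",
         c(0, 0, -L("calf_r")), list(R1 = ey, R2 = ex), 30, 3, c(-1, 1)))
  names(joints) <- vapply(joints, `[[`, "", "name")
  structure(list(
    stature = H, segments = seg, joints = joints,
    thigh_len = L("thigh_l"), calf_len = L("calf_l"),
    hip_halfwidth = hipw, ankle_height = ANKLE_HEIGHT_FRAC * H,
    hip_height = L("thigh_l") + L("calf_l") + ANKLE_HEIGHT_FRAC * H),
    class = "skeleton_topology")
}

#' Assemble an articulated pedestrian model
#'
#' Scales the 15-segment skeleton to a stature and total mass: segment
#' lengths from stature fractions, segment masses from mass fractions
#' (summing exactly to the total), inertia tensors from solid-primitive
#' formulas (solid cylinders for limbs/trunk, sphere for the head), and
#' capsule collision geometry per segment.
#'
#' @param stature stature, m (1.4--2.1).
#' @param mass total body mass, kg (40--120).
#' @param topology optional [skeleton_topology()]; defaults to one scaled
#'   to `stature`.
#' @return object of class `"pedestrian_model"` with per-segment mass,
#'   COM offset (segment frame), inertia about the COM, capsule geometry
#'   and the joint tree.
#' @export
pedestrian_model <- function(stature = 1.74, mass = 68,
                             topology = skeleton_topology(stature)) {
  check_number(stature, "stature", 1.4, 2.1)
  check_number(mass, "mass", 40, 120)
  seg <- topology$segments
  seg$mass <- seg$mass_frac * mass
  n <- nrow(seg)
  com <- matrix(0, n, 3, dimnames = list(seg$name, c("x", "y", "z")))
  inertia <- vector("list", n); names(inertia) <- seg$name
  cap0 <- matrix(0, n, 3); cap1 <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    nm <- seg$name[i]; len <- seg$length[i]; r <- seg$radius[i]
    m <- seg$mass[i]; cf <- seg$com_frac[i]
    up <- nm %in% c("pelvis", "lower_trunk", "upper_trunk", "neck", "head")
    if (nm %in% c("foot_l", "foot_r")) {
      ## foot: origin at the ankle; extends forward, sole below
      dz <- -topology$ankle_height + r
      com[i, ] <- c(0.25 * len, 0, dz)
      cap0[i, ] <- c(-0.25 * len, 0, dz)
      cap1[i, ] <- c(0.7 * len, 0, dz)
      Iax <- m * r^2 / 2
      Itr <- m * (3 * r^2 + len^2) / 12
      inertia[[i]] <- diag(c(Iax, Itr, Itr))
    } else if (nm == "head") {
      rad <- r
      com[i, ] <- c(0, 0, cf * len)
      cap0[i, ] <- c(0, 0, cf * len); cap1[i, ] <- c(0, 0, cf * len)
      inertia[[i]] <- diag(rep(2 / 5 * m * rad^2, 3))
    } else {
      s <- if (up) 1 else -1
      com[i, ] <- c(0, 0, s * cf * len)
      cap0[i, ] <- c(0, 0, if (up) 0.05 * len else -0.05 * len)
      cap1[i, ] <- c(0, 0, s * 0.95 * len)
      Iax <- m * r^2 / 2
      Itr <- m * (3 * r^2 + len^2) / 12
      inertia[[i]] <- diag(c(Itr, Itr, Iax))
    }
  }
  structure(list(stature = stature, mass = mass, topology = topology,
                 segments = seg, com_offset = com, inertia = inertia,
                 capsule_p0 = cap0, capsule_p1 = cap1,
                 capsule_r = seg$radius),
            class = "pedestrian_model")
}

#' @export
print.pedestrian_model <- function(x, ...) {
  cat(sprintf(
    "Articulated pedestrian: stature %.2f m, mass %.2f kg\n",
    x$stature, x$mass))
  cat(sprintf("  %d segments, %d joints (+ 6-DOF floating base)\n",
              nrow(x$segments), length(x$topology$joints)))
  invisible(x)
}
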