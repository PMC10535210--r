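# Cubic-spline joint planning and inverse kinematics

test_that("clamped spline interpolates knots with C2 interior joins", {
  x <- c(0, 0.3, 0.7, 1.1, 1.5)
  y <- c(0, 0.5, -0.2, 0.8, 0.1)
  sp <- clamped_spline(x, y, deriv_left = 0, deriv_right = 0)
  expect_equal(spline_eval(sp, x), y, tolerance = 1e-12)
  expect_equal(spline_eval(sp, x[1L], 1L), 0, tolerance = 1e-10)
  expect_equal(spline_eval(sp, x[5L], 1L), 0, tolerance = 1e-10)
  for (k in 2:4) {
    lo <- spline_eval(sp, x[k] - 1e-9, 2L)
    hi <- spline_eval(sp, x[k] + 1e-9, 2L)
    expect_lt(abs(hi - lo), 1e-5)
  }
})

test_that("two-link IK returns the knee-forward closed-form solution", {
  ## straight leg at full extension, flagged near-singular
  ik <- solve_leg_ik(c(0, 1), c(0, 0), 0.5, 0.5)
  expect_equal(ik[["knee_R1"]], 0, tolerance = 1e-9)
  expect_true(attr(ik, "near_singular"))
  ## isoceles triangle: hip-foot distance equal to one link
  ik2 <- solve_leg_ik(c(0, 0.5), c(0, 0), 0.5, 0.5)
  expect_equal(ik2[["knee_R1"]], 2 * pi / 3, tolerance = 1e-12)
  expect_error(solve_leg_ik(c(0, 2), c(0, 0), 0.5, 0.5), "out of reach")
})

test_that("FK inverts IK on random reachable targets", {
  set.seed(42)
  l1 <- 0.426; l2 <- 0.428
  worst <- 0
  for (i in 1:1000) {
    r <- runif(1, abs(l1 - l2) + 1e-3, (l1 + l2) - 1e-6)
    th <- runif(1, -pi, pi)
    target <- r * c(sin(th), -cos(th))
    ik <- solve_leg_ik(c(0, 0), target, l1, l2)
    fk <- leg_fk(c(0, 0), ik[["hip_R2"]], ik[["knee_R1"]], l1, l2)
    worst <- max(worst, sqrt(sum((fk$ankle - target)^2)))
  }
  expect_lt(worst, 1e-9)
})

test_that("swing foot splines hit footholds and the clearance apex", {
  g <- adult_gait(4.5)
  fp <- plan_foot_trajectory(g, swing_clearance = 0.1, ankle_height = 0)
  sw <- fp$swings[["0"]]
  ## knot interpolation at lift-off and touchdown
  expect_equal(spline_eval(sw$sx, sw$t_lo), fp$fh0, tolerance = 1e-9)
  expect_equal(spline_eval(sw$sx, sw$t_td), fp$fh0 + 2 * fp$SL,
               tolerance = 1e-9)
  ## zero velocity at both ends
  expect_equal(spline_eval(sw$sx, sw$t_lo, 1L), 0, tolerance = 1e-9)
  expect_equal(spline_eval(sw$sz, sw$t_td, 1L), 0, tolerance = 1e-9)
  ## mid-swing height equals the clearance exactly
  tm <- (sw$t_lo + sw$t_td) / 2
  expect_equal(spline_eval(sw$sz, tm), 0.1, tolerance = 1e-9)
  expect_error(plan_foot_trajectory(g, swing_clearance = 2), "clearance")
})

test_that("degenerate zero-step swing is a vertical arc", {
  g <- adult_gait(4.5)
  g$step_length <- 0
  fp <- plan_foot_trajectory(g, swing_clearance = 0.08)
  sw <- fp$swings[["0"]]
  tt <- seq(sw$t_lo, sw$t_td, length.out = 30)
  expect_true(all(abs(spline_eval(sw$sx, tt) - fp$fh0) < 1e-9))
})

test_that("arm swing is anti-phase with the ipsilateral leg", {
  g <- adult_gait(4.5)
  ap <- plan_arm_swing(g, amplitude = 0.4)
  T <- ap$T
  tt <- seq(0, T, length.out = 400)
  sl <- spline_eval(ap$shoulder_l, tt)
  ## left shoulder extremum near the right-hip extremum time (t = T/2)
  expect_lt(abs(tt[which.min(sl)] - T / 2), T / 50)
  ## zero amplitude gives constant arms
  ap0 <- plan_arm_swing(g, amplitude = 0)
  expect_true(all(abs(spline_eval(ap0$shoulder_l, tt)) < 1e-12))
})

test_that("joint trajectory: COM tracking, stance anchoring, symmetry", {
  g <- adult_gait(4.5)
  topo <- adult_topology()
  model <- adult_model()
  tr <- adult_trajectory()
  ct <- compose_gait(g, 3L, 1e-3)
  tt <- seq(0, tr$stride_period, length.out = 40)
  ## mass-weighted COM of the posed body tracks the virtual-leg centroid
  err <- vapply(tt, function(t) {
    qs <- as.list(vapply(colnames(tr$channels), function(ch)
      spline_eval(tr$splines[[ch]], t), 0))
    pel <- c(spline_eval(tr$pelvis_x, t), spline_eval(tr$pelvis_z, t))
    cm <- pedrecon:::planner_com(model, pel, tr$trunk_pitch, qs)
    tgt <- c(stats::approx(ct$time, ct$com_x, t)$y,
             stats::approx(ct$time, ct$com_z, t)$y)
    sqrt(sum((cm - tgt)^2))
  }, 0)
  expect_lt(max(err), 0.05 * g$params$q_r0)
  ## stance-foot anchoring: ankle from FK at the planner knots stays on
  ## the foothold (the knot states are exact-IK; between knots the spline
  ## interpolates)
  t_st <- g$stance$time[nrow(g$stance)]
  ts <- tr$time[tr$time > 0.02 * t_st & tr$time < 0.98 * t_st]
  fh <- attr(g$stance, "foothold")
  drift <- vapply(ts, function(t) {
    pel <- c(spline_eval(tr$pelvis_x, t), spline_eval(tr$pelvis_z, t))
    fk <- leg_fk(pel, spline_eval(tr$splines[["HipL.R2"]], t),
                 spline_eval(tr$splines[["KneeL.R1"]], t),
                 topo$thigh_len, topo$calf_len, tr$trunk_pitch)
    abs(fk$ankle[1L] - fh[1L])
  }, 0)
  expect_lt(max(drift), 1e-6)
  ## bilateral symmetry: right series equals left shifted by half stride
  ## (half a stride is exactly (n_grid - 1)/2 knot intervals)
  sh <- (length(tr$time) - 1L) / 2L
  idx <- seq_len(length(tr$time) - sh)
  dl <- tr$channels[idx + sh, "HipL.R2"] - tr$channels[idx, "HipR.R2"]
  expect_lt(max(abs(dl)), 1e-6)
  ## channel splines are C2 at interior knots
  kn <- tr$time[5:10]
  for (ch in c("HipL.R2", "KneeL.R1")) {
    jump <- abs(spline_eval(tr$splines[[ch]], kn + 1e-9, 2L) -
                  spline_eval(tr$splines[[ch]], kn - 1e-9, 2L))
    expect_lt(max(jump), 1e-5)
  }
})

test_that("ten-phase sampling returns exactly ten postures", {
  tr <- adult_trajectory()
  ps <- pose_strip(tr, 10L)
  expect_length(ps, 10L)
  expect_true(all(vapply(ps, inherits, TRUE, "pose")))
})

test_that("sampled pose velocities match finite differences of angles", {
  tr <- adult_trajectory()
  t0 <- 0.3 * tr$stride_period
  dt <- 1e-5
  pa <- sample_pose(tr, t0 - dt); pb <- sample_pose(tr, t0 + dt)
  p <- sample_pose(tr, t0)
  fd <- (pb$joints$R1_rad[pb$joints$joint == "KneeL"] -
           pa$joints$R1_rad[pa$joints$joint == "KneeL"]) / (2 * dt)
  sr <- attr(p, "signed_rates")[["KneeL.R1"]]
  expect_equal(sr, fd, tolerance = 1e-4)
  expect_error(sample_pose(tr, -1), "outside")
})

test_that("the shipped collision-moment pose fixture round-trips", {
  pose <- read_pose(pedrecon_fixture("table2_pose.csv"))
  expect_equal(pose$joints$R1_rad[pose$joints$joint == "KneeR"], 1.37)
  expect_equal(
    pose$body_parts$angular_velocity_rad_per_s[
      pose$body_parts$body_part == "Left calf"], 4.7907)
  f <- tempfile(fileext = ".csv")
  write_pose(pose, f)
  ## byte-stable round trip against the shipped file
  expect_identical(readLines(f), readLines(pedrecon_fixture("table2_pose.csv")))
  pose2 <- read_pose(f)
  expect_equal(pose2$joints, pose$joints)
  expect_equal(pose2$body_parts, pose$body_parts)
  unlink(f)
})
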