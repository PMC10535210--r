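# Articulated rigid-flexible multibody dynamics

test_that("assembled pedestrian conserves and scales mass", {
  m <- adult_model()
  expect_equal(sum(m$segments$mass), 68, tolerance = 68 * 1e-3)
  m2 <- pedestrian_model(1.74, 100)
  expect_equal(m2$segments$mass, m$segments$mass * 100 / 68,
               tolerance = 1e-12)
  expect_error(pedestrian_model(1.0, 68), "stature")
  expect_error(pedestrian_model(1.74, 200), "mass")
})

test_that("standing COM height sits in the anthropometric band", {
  ## independent oracle: mass-weighted sum over the documented fraction
  ## table (standing, all segments vertical)
  tab <- pedrecon:::SEGMENT_TABLE
  H <- 1.74
  hip_z <- (0.245 + 0.246 + 0.039) * H
  z <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    nm <- tab$name[i]; len <- tab$len_frac[i] * H; cf <- tab$com_frac[i]
    z[i] <- switch(nm,
      pelvis = hip_z + cf * len,
      lower_trunk = hip_z + 0.078 * H + cf * len,
      upper_trunk = hip_z + (0.078 + 0.081) * H + cf * len,
      neck = hip_z + (0.078 + 0.081 + 0.129) * H + cf * len,
      head = hip_z + (0.078 + 0.081 + 0.129 + 0.052) * H + cf * len,
      upper_arm_l = , upper_arm_r =
        hip_z + (0.078 + 0.081 + 0.9 * 0.129) * H - cf * len,
      lower_arm_l = , lower_arm_r =
        hip_z + (0.078 + 0.081 + 0.9 * 0.129) * H - 0.186 * H - cf * len,
      thigh_l = , thigh_r = hip_z - cf * len,
      calf_l = , calf_r = hip_z - 0.245 * H - cf * len,
      foot_l = , foot_r = 0.02 * H)
  }
  com_frac <- sum(tab$mass_frac * z) / H
  expect_gt(com_frac, 0.55)
  expect_lt(com_frac, 0.60)
  ## the assembled model (grounded standing pose) agrees with the oracle
  mb <- adult_mb()
  st <- apply_pose(mb, pedrecon:::standing_pose())
  cm <- pedrecon:::mb_com(mb, st$q)$com
  expect_equal(cm[3L] / H, com_frac, tolerance = 0.03)
})

test_that("generalized force arrays vanish in static neutral zero-g", {
  mb <- adult_mb()
  gf <- generalized_forces(mb, numeric(mb$nb), numeric(mb$nb),
                           a = c(0, 0), ad = c(0, 0), gravity = 0)
  expect_true(all(abs(unlist(gf$inertial)) < 1e-12))
  expect_true(all(abs(gf$active) < 1e-9))
  expect_true(all(gf$elastic == 0))
})

test_that("principal-axis spin has zero gyroscopic force", {
  ch <- pedrecon:::mb_custom(list(
    list(type = "r", axis = c(0, 0, 1), origin = c(0, 0, 0), mass = 2,
         com = c(0, 0, 0), inertia = diag(c(0.1, 0.2, 0.3)),
         name = "spin")), gravity = 0)
  gf <- generalized_forces(ch, q = 0.4, qd = 7, gravity = 0)
  expect_true(all(abs(gf$inertial$spin) < 1e-12))
})

test_that("flexible restoring force follows -K a - C a'", {
  mb <- adult_mb()
  gf <- generalized_forces(mb, numeric(mb$nb), numeric(mb$nb),
                           a = c(0.02, 0), ad = c(0, 0))
  expect_equal(gf$elastic[1L], -mb$modes$K[1L] * 0.02)
  expect_equal(gf$elastic[2L], 0)
})

test_that("whole-body free fall matches the ballistic oracle", {
  mb <- adult_mb()
  st <- mb_state0(mb)
  z0 <- pedrecon:::mb_com(mb, st$q)$com[3L]
  for (i in 1:100) st <- mb_step(st, mb, dt = 5e-3, method = "rk4")
  z1 <- pedrecon:::mb_com(mb, st$q)$com[3L]
  expect_equal(z0 - z1, 0.5 * 9.81 * 0.5^2, tolerance = 1e-10)
  ## no internal joint motion develops
  expect_lt(max(abs(st$q[-(1:6)])), 1e-10)
})

test_that("single pendulum matches the analytic small-angle solution", {
  l <- 0.5; m <- 2
  pend <- pedrecon:::mb_custom(list(
    list(type = "r", axis = c(0, 1, 0), origin = c(0, 0, 0), mass = m,
         com = c(0, 0, -l), inertia = diag(1e-9, 3), name = "rod")))
  th0 <- 0.05
  st <- mb_state0(pend, q = th0)
  dt <- 1e-3
  qs <- numeric(1000)
  for (i in 1:1000) {
    st <- mb_step(st, pend, dt = dt, method = "rk4")
    qs[i] <- st$q
  }
  w <- sqrt(9.81 / l)
  expect_lt(max(abs(qs - th0 * cos(w * (1:1000) * dt))), 1e-3)
})

test_that("isolated chain conserves linear and angular momentum", {
  ch <- two_link_chain(k = 5, gravity = 0)
  st <- mb_state0(ch, q = c(0, 0, 0, 0, 0, 0.3, 0.4),
                  qd = c(1, 0.2, 0.5, 0.3, 0, 1.0, -2.0))
  p0 <- pedrecon:::mb_momentum(ch, st$q, st$qd)
  for (i in 1:2000) st <- mb_step(st, ch, dt = 5e-4, method = "rk4",
                                  gravity = 0)
  p1 <- pedrecon:::mb_momentum(ch, st$q, st$qd)
  expect_lt(max(abs(p1$linear - p0$linear)) / max(abs(p0$linear)), 1e-8)
  expect_lt(max(abs(p1$angular - p0$angular)) / max(abs(p0$angular)), 1e-8)
})

test_that("damped flexible mode energy decays monotonically", {
  mb <- adult_mb()
  st <- mb_state0(mb)
  st$a <- c(0.05, 0); st$ad <- c(0, 0)
  E <- numeric(200)
  for (i in 1:200) {
    st <- mb_step(st, mb, dt = 1e-4, gravity = 0)
    E[i] <- 0.5 * mb$modes$K[1L] * st$a[1L]^2 +
      0.5 * mb$modes$mass[1L] * st$ad[1L]^2
  }
  ## energy envelope decreases (allow tiny numerical ripple)
  expect_true(all(diff(E) < 1e-8))
  expect_lt(E[200], E[1])
})

test_that("pose application sets the COM velocity exactly", {
  mb <- adult_mb()
  pose <- read_pose(pedrecon_fixture("table2_pose.csv"))
  expect_no_warning(st <- apply_pose(mb, pose,
                                     com_velocity = c(4.5, 0, 0)))
  v <- pedrecon:::mb_com(mb, st$q, st$qd)$vel
  expect_equal(v, c(4.5, 0, 0), tolerance = 1e-9)
  ## lowest collision surface rests on the ground
  cp <- pedrecon:::capsule_points(mb, st$q)
  expect_equal(min(cp[, 3L] - attr(cp, "radius")), 0, tolerance = 1e-9)
  ## zero pose, zero velocity: standing still
  st0 <- apply_pose(mb, pedrecon:::standing_pose())
  ke <- sum(abs(st0$qd))
  expect_equal(ke, 0)
})

test_that("a pose outside the joint limits is clamped with a warning", {
  mb <- adult_mb()
  pose <- read_pose(pedrecon_fixture("table2_pose.csv"))
  pose$joints$R1_rad[pose$joints$joint == "KneeR"] <- 3.1
  expect_warning(st <- apply_pose(mb, pose), "clamped")
  expect_lte(st$q[mb$chan_idx[["KneeR.R1"]]], 2.6)
})

test_that("segment frames stay mutually consistent during motion", {
  ## FK closure: child joint origin computed from the parent frame
  ## coincides with the child frame origin
  mb <- adult_mb()
  pose <- read_pose(pedrecon_fixture("table2_pose.csv"))
  st <- apply_pose(mb, pose, com_velocity = c(3, 0, 0))
  for (i in 1:20) st <- mb_step(st, mb, dt = 1e-3, gravity = 0)
  fk <- pedrecon:::mb_fk(mb, st$q)
  worst <- 0
  for (i in seq_len(mb$nb)) {
    p <- mb$parent[i]
    if (p == 0L) next
    je <- pedrecon:::joint_ErS(mb, i, st$q[i])
    pred <- fk$r[[p]] + as.numeric(t(fk$E[[p]]) %*% je$r)
    worst <- max(worst, max(abs(pred - fk$r[[i]])))
  }
  expect_lt(worst, 1e-9)
})
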