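# Contact curves, narrow phase and friction

test_that("contact curve validates and evaluates piecewise linearly", {
  cc <- contact_curve(c(0, 0.05, 0.2), c(0, 5000, 20000), 0.5)
  expect_equal(curve_force(cc, 0), 0)
  expect_equal(curve_force(cc, 0.025), 2500)   # inside first linear piece
  expect_equal(curve_force(cc, 0.2), 20000)
  ## beyond the domain: last-slope extrapolation, flagged
  f <- curve_force(cc, 0.3)
  expect_equal(as.numeric(f), 20000 + 1e5 * 0.1)
  expect_true(isTRUE(attr(f, "extrapolated")))
  expect_error(contact_curve(c(0.01, 0.1), c(0, 1)), "start at")
  expect_error(contact_curve(c(0, 0.1), c(0, -1)), "non-decreasing")
})

test_that("no contacts are reported far from every surface", {
  mb <- adult_mb()
  st <- apply_pose(mb, pedrecon:::standing_pose())
  st$q[mb$chan_idx[["base.z"]]] <- st$q[mb$chan_idx[["base.z"]]] + 5
  prof <- sedan_profile()
  vs <- list(position = c(10, 10), heading = 0, velocity = c(0, 0, 0))
  ct <- detect_contacts(mb, st, prof, vs, ground_z = 0)
  expect_null(ct)
})

test_that("sphere-on-ground penetration is exact", {
  mb <- adult_mb()
  st <- apply_pose(mb, pedrecon:::standing_pose())
  ## push down by delta: the foot spheres penetrate by exactly delta
  delta <- 0.013
  st$q[mb$chan_idx[["base.z"]]] <- st$q[mb$chan_idx[["base.z"]]] - delta
  ct <- detect_contacts(mb, st)
  expect_false(is.null(ct))
  expect_true(all(ct$penetration > 0))
  expect_equal(max(ct$penetration), delta, tolerance = 1e-9)
  expect_true(all(ct$nz == 1))
})

test_that("capsule grazing the profile finds the outline point", {
  prof <- sedan_profile()
  ## brute-force closest point on a dense outline sampling
  st <- prof$stations
  dense <- NULL
  for (s in seq_len(nrow(st) - 1L)) {
    tt <- seq(0, 1, length.out = 4000)
    dense <- rbind(dense, cbind(st$x[s] + tt * (st$x[s + 1L] - st$x[s]),
                                st$z[s] + tt * (st$z[s + 1L] - st$z[s])))
  }
  for (p in list(c(0.05, 0.45), c(-0.5, 1.05), c(-1.4, 1.3))) {
    pc <- pedrecon:::profile_closest(prof, p[1L], p[2L])
    dd <- sqrt((dense[, 1L] - p[1L])^2 + (dense[, 2L] - p[2L])^2)
    expect_equal(pc$dist, min(dd), tolerance = 1e-5)
  }
})

test_that("contact force obeys the friction cone and branch rules", {
  cc <- contact_curve(c(0, 0.1), c(0, 10000), hysteresis = 0.6)
  row <- list(nx = 0, ny = 0, nz = 1, vrx = 1.3, vry = -0.4, vrz = -0.2,
              penetration = 0.05)
  f <- contact_force(row, cc, mu = 0.6)
  fn <- attr(f, "normal_mag"); ft <- attr(f, "tangential_mag")
  expect_equal(fn, 5000)            # loading branch (penetrating)
  expect_lte(ft, 0.6 * fn + 1e-9)
  ## unloading branch: separating contact carries the hysteresis factor
  row$vrz <- 0.2
  f2 <- contact_force(row, cc, mu = 0.6)
  expect_equal(attr(f2, "normal_mag"), 0.6 * 5000)
  ## zero penetration gives zero force
  row$penetration <- 0
  expect_equal(as.numeric(contact_force(row, cc, mu = 0.6)), c(0, 0, 0))
})

test_that("friction cone holds across random contact states", {
  set.seed(7)
  cc <- contact_curve(c(0, 0.1, 0.3), c(0, 8000, 30000), 0.4)
  for (i in 1:200) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    row <- list(nx = n[1], ny = n[2], nz = n[3],
                vrx = rnorm(1, 0, 3), vry = rnorm(1, 0, 3),
                vrz = rnorm(1, 0, 3), penetration = runif(1, 0, 0.4))
    f <- contact_force(row, cc, mu = 0.5)
    expect_lte(attr(f, "tangential_mag"),
               0.5 * attr(f, "normal_mag") + 1e-9)
  }
})

test_that("hysteresis loop dissipates the analytic trapezoid area", {
  ## two-slope loading curve, load to a fixed peak then unload
  cc <- contact_curve(c(0, 0.1, 0.2), c(0, 1000, 4000), hysteresis = 0.55)
  peak <- 0.18
  dd <- seq(0, peak, length.out = 4001)
  load <- pedrecon:::trapz(dd, curve_force(cc, dd))
  unload <- 0.55 * load
  loop <- load - unload
  ## analytic: area under the two-slope curve up to the peak
  a1 <- 0.5 * 0.1 * 1000
  a2 <- 0.5 * (1000 + curve_force(cc, peak)) * (peak - 0.1)
  expect_equal(loop, (1 - 0.55) * (a1 + a2), tolerance = 1e-6)
  expect_gte(loop, 0)
})

test_that("rebound height is bounded by the hysteresis factor", {
  ## a single-sphere body dropped on the ground
  h <- 0.4
  drop <- 0.5
  ball <- pedrecon:::mb_custom(list(
    list(type = "p", axis = c(0, 0, 1), origin = c(0, 0, 0), mass = 1,
         com = c(0, 0, 0), inertia = diag(1e-4, 3), radius = 0.1,
         name = "ball")))
  cc <- contact_curve(c(0, 0.2), c(0, 6000), hysteresis = h)
  st <- mb_state0(ball, q = drop + 0.1)
  zmax <- 0
  phase2 <- FALSE
  loads <- function(t, q, qd) {
    pen <- 0.1 - q
    if (pen <= 0) return(list(f_ext = list(), modal = numeric(0)))
    row <- list(nx = 0, ny = 0, nz = 1, vrx = 0, vry = 0, vrz = qd,
                penetration = pen)
    f <- contact_force(row, cc, mu = 0)
    list(f_ext = list(ball = c(0, 0, 0, f)), modal = numeric(0))
  }
  for (i in 1:20000) {
    st <- mb_step(st, ball, loads = loads, dt = 5e-5)
    if (st$qd > 0) phase2 <- TRUE
    if (phase2) zmax <- max(zmax, st$q)
    if (phase2 && st$qd < 0) break
  }
  rebound <- zmax - 0.1
  expect_lte(rebound, h * drop * 1.02)
  expect_gt(rebound, 0.1 * drop)   # it does bounce
})

test_that("contact curve CSV fixture loads through the reader", {
  cc <- read_contact_curve_csv(pedrecon_fixture("contact_curve_example.csv"))
  expect_s3_class(cc, "contact_curve")
  expect_equal(curve_force(cc, 0.03), 6000)
})
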