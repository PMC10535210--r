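# Virtual-leg (SLIP) centroid dynamics

test_that("stance accelerations solve the equations of motion", {
  p <- adult_params()
  ## vertical uncompressed rest configuration: only gravity acts
  st <- list(q_r = p$q_r0, q_theta = 0, dq_r = 0, dq_theta = 0)
  dd <- stance_derivatives(st, p)
  expect_equal(dd[["ddq_theta"]], 0)
  expect_equal(dd[["ddq_r"]], -p$g)
  ## spring compressed by the static deflection: spring adds exactly +g
  st2 <- list(q_r = p$q_r0 + p$m * p$g / p$k_r, q_theta = 0, dq_r = 0,
              dq_theta = 0)
  expect_equal(stance_derivatives(st2, p)[["ddq_r"]], -2 * p$g)
  ## frozen computer-algebra evaluation of the full equations
  p3 <- slip_params(mass = 68, stiffness = 20000, rest_length = 1)
  st3 <- list(q_r = 0.95, q_theta = 0.2, dq_r = -0.5, dq_theta = 1.0)
  dd3 <- stance_derivatives(st3, p3)
  expect_equal(dd3[["ddq_r"]], 6.0414292243185961, tolerance = 1e-12)
  expect_equal(dd3[["ddq_theta"]], 3.1041538264205795, tolerance = 1e-12)
  expect_error(stance_derivatives(list(q_r = -0.1, q_theta = 0, dq_r = 0,
                                       dq_theta = 0), p3), "singular")
})

test_that("vertical spring bounce conserves speed and energy", {
  p <- adult_params()
  s0 <- slip_state(p$q_r0, 0, -1.5, 0)
  tr <- integrate_stance(s0, p)
  expect_identical(attr(tr, "terminating_event"), "liftoff")
  n <- nrow(tr)
  expect_equal(abs(tr$dq_r[n]), 1.5, tolerance = 1e-6)
  expect_true(all(abs(tr$com_x - tr$com_x[1L]) < 1e-9))
  E <- pedrecon:::slip_energy(tr$q_r, tr$q_theta, tr$dq_r, tr$dq_theta, p)
  expect_lt((max(E) - min(E)) / mean(E), 1e-6)
})

test_that("asymmetric stance mirrors under angle/rate sign flip", {
  p <- adult_params()
  a <- integrate_stance(slip_state(p$q_r0, -0.25, -1.2, 4.0), p)
  b <- integrate_stance(slip_state(p$q_r0, 0.25, -1.2, -4.0), p)
  n <- min(nrow(a), nrow(b))
  expect_equal(a$q_r[seq_len(n)], b$q_r[seq_len(n)], tolerance = 1e-7)
  expect_equal(a$q_theta[seq_len(n)], -b$q_theta[seq_len(n)],
               tolerance = 1e-7)
})

test_that("flight phase follows the ballistic closed form", {
  p <- adult_params()
  p$touchdown_angle <- 0.25
  z_td <- p$q_r0 * cos(0.25)
  ini <- list(com = c(0, z_td + 0.06), vel = c(4.0, 1.0), time = 0)
  tr <- integrate_flight(ini, p)
  expect_identical(attr(tr, "terminating_event"), "touchdown")
  tt <- tr$time
  expect_equal(tr$com_x, 0 + 4.0 * tt, tolerance = 1e-12)
  expect_equal(tr$com_z, z_td + 0.06 + 1.0 * tt - 0.5 * p$g * tt^2,
               tolerance = 1e-12)
  ## horizontal momentum constant at every sample
  expect_true(all(tr$vx == 4.0))
  ## zero-duration case: descending at touchdown height
  tr0 <- integrate_flight(list(com = c(0, z_td - 1e-12), vel = c(4, 0),
                               time = 0), p)
  expect_equal(nrow(tr0), 1L)
  ## symmetric-landing projectile time: start at touchdown height going up
  tr2 <- integrate_flight(list(com = c(0, z_td), vel = c(4, 1), time = 0),
                          p)
  expect_equal(tr2$time[nrow(tr2)], 2 * 1 / p$g, tolerance = 1e-10)
})

test_that("periodic gait recovers commanded speeds within 1 %", {
  for (v in c(4.5, 4.168)) {
    g <- adult_gait(v)
    expect_lt(abs(g$mean_forward_speed - v) / v, 0.01)
    ## stance energy conservation inside the cycle
    st <- g$stance
    E <- pedrecon:::slip_energy(st$q_r, st$q_theta, st$dq_r, st$dq_theta,
                                g$params)
    expect_lt((max(E) - min(E)) / mean(E), 1e-6)
  }
})

test_that("the gait is a limit cycle: apex recurrence over 5 cycles", {
  g <- adult_gait(4.5)
  p <- g$params
  apex_z <- function(stance_end) {
    stance_end$com[2L] + stance_end$vel[2L]^2 / (2 * p$g)
  }
  ## re-integrate 5 cycles from the stored touchdown state
  st <- g$stance[1L, ]
  s <- slip_state(st$q_r, st$q_theta, st$dq_r, st$dq_theta,
                  foothold = attr(g$stance, "foothold"))
  drift <- 0
  for (k in 1:5) {
    tr <- integrate_stance(s, p, tol = g$tol)
    n <- nrow(tr)
    za <- tr$com_z[n] + tr$vz[n]^2 / (2 * p$g)
    drift <- max(drift, abs(za - g$apex_height))
    fl <- integrate_flight(list(com = c(tr$com_x[n], tr$com_z[n]),
                                vel = c(tr$vx[n], tr$vz[n]),
                                time = tr$time[n]), p)
    m <- nrow(fl)
    qt <- -g$touchdown_angle
    dq_r <- fl$vx[m] * sin(qt) + fl$vz[m] * cos(qt)
    dq_th <- (fl$vx[m] * cos(qt) - fl$vz[m] * sin(qt)) / p$q_r0
    s <- slip_state(p$q_r0, qt, dq_r, dq_th,
                    foothold = c(fl$com_x[m] - p$q_r0 * sin(qt), 0))
  }
  expect_lt(drift, 10 * max(g$tol, 1e-6))
})

test_that("touchdown angle maps monotonically to steady speed", {
  g <- adult_gait(4.5)
  ## speed at a slightly larger and smaller touchdown angle bracket the
  ## solved speed in opposite directions (numerical monotonicity)
  sp <- vapply(c(3.0, 4.5, 6.0), function(v) adult_gait(v)$touchdown_angle,
               0)
  expect_true(all(diff(sp) > 0) || all(diff(sp) < 0))
})

test_that("composed gait tiles the cycle continuously", {
  g <- adult_gait(4.5)
  tr <- compose_gait(g, n_steps = 3L, dt_out = 1e-3)
  expect_equal(max(tr$com_x) - tr$com_x[1L], 3 * g$step_length,
               tolerance = 0.02)
  ## C0/C1 continuity across every sample (phase joins included)
  dvx <- abs(diff(tr$vx)); dvz <- abs(diff(tr$vz))
  expect_lt(max(dvx), 0.2)  # bounded by accel * dt, no jumps
  expect_lt(max(dvz), 0.2)
  tr1 <- compose_gait(g, n_steps = 1L, dt_out = 1e-3)
  expect_equal(nrow(tr1), length(seq(0, g$step_period, by = 1e-3)))
  expect_error(compose_gait(g, n_steps = 0L), "n_steps")
})

test_that("speed targeting recovers across the running range", {
  for (v in c(2.5, 6)) {
    g <- slip_gait(adult_params(), v)
    expect_lt(abs(g$mean_forward_speed - v) / v, 0.01)
  }
})

test_that("gait CSV export has the documented header", {
  g <- adult_gait(4.5)
  f <- tempfile(fileext = ".csv")
  write_gait_csv(compose_gait(g, 1L), f)
  hdr <- names(utils::read.csv(f))
  expect_identical(hdr, c("time_s", "phase", "com_x_m", "com_z_m",
                          "vx_mps", "vz_mps", "q_r_m", "q_theta_rad"))
  unlink(f)
})
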