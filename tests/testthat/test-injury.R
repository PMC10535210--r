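# Injury criteria: HIC, chest 3 ms clip, bone stress proxy

## independent brute-force HIC: double loop over all sample pairs
hic_brute <- function(t, a, wmax) {
  ct <- pedrecon:::cumtrapz(t, a)
  best <- 0
  n <- length(t)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    T <- t[j] - t[i]
    if (T > wmax + 1e-12) break
    v <- T * ((ct[j] - ct[i]) / T)^2.5
    if (v > best) best <- v
  }
  best
}

test_that("HIC matches the closed form for a constant pulse", {
  tt <- seq(0, 0.1, by = 1e-4)
  a <- ifelse(tt >= 0.02 - 1e-9 & tt <= 0.035 + 1e-9, 100, 0)
  tr <- accel_trace(tt, a)
  h <- hic(tr, max_window = 0.036)
  expect_equal(h$value, 100^2.5 * 0.015, tolerance = 1e-6)
  expect_lte(h$t2 - h$t1, 0.036 + 1e-9)
  ## all-zero trace
  expect_equal(hic(accel_trace(tt, rep(0, length(tt))))$value, 0)
  expect_error(hic(accel_trace(0.1, 5)), "too short")
})

test_that("HIC agrees with brute-force search on a half-sine pulse", {
  tt <- seq(0, 0.06, by = 2e-4)
  a <- ifelse(tt < 0.03, 80 * sin(pi * tt / 0.03), 0)
  tr <- accel_trace(tt, a)
  h <- hic(tr, 0.036)
  hb <- hic_brute(tt, a, 0.036)
  expect_equal(h$value, hb, tolerance = 1e-3)
})

test_that("HIC invariances: time shift and amplitude scaling", {
  tt <- seq(0, 0.05, by = 1e-4)
  a <- 50 * exp(-((tt - 0.02) / 0.005)^2)
  h1 <- hic(accel_trace(tt, a), 0.036)$value
  h2 <- hic(accel_trace(tt + 1.7, a), 0.036)$value
  expect_equal(h1, h2, tolerance = 1e-12)
  h3 <- hic(accel_trace(tt, 2 * a), 0.036)$value
  expect_equal(h3, 2^2.5 * h1, tolerance = 1e-9)
  ## grid refinement convergence: halving dt changes the value < 0.1 %
  tt2 <- seq(0, 0.05, by = 5e-5)
  a2 <- 50 * exp(-((tt2 - 0.02) / 0.005)^2)
  h4 <- hic(accel_trace(tt2, a2), 0.036)$value
  expect_lt(abs(h4 - h1) / h1, 1e-3)
})

test_that("chest 3 ms clip is the max sustained level", {
  tt <- seq(0, 0.02, by = 1e-4)
  expect_equal(chest_3ms(accel_trace(tt, rep(60, length(tt)))), 60)
  ## 1 ms spike on a 20 g baseline is ignored by the 3 ms window
  a <- rep(20, length(tt)); a[tt >= 0.008 & tt < 0.009] <- 80
  expect_equal(chest_3ms(accel_trace(tt, a)), 20)
  ## triangular pulse vs brute-force sliding minimum
  atri <- pmax(0, 70 - abs(tt - 0.01) * 8000)
  tr <- accel_trace(tt, atri)
  k <- ceiling(0.003 / 1e-4) + 1L
  brute <- max(vapply(seq_len(length(tt) - k + 1L),
                      function(i) min(atri[i:(i + k - 1L)]), 0))
  expect_equal(chest_3ms(tr), brute)
  ## clip never exceeds the global maximum
  expect_lte(chest_3ms(tr), max(atri))
  expect_error(chest_3ms(accel_trace(c(0, 1e-3), c(1, 1))), "shorter")
})

test_that("beam stress proxy matches the closed form", {
  ## frozen symbolic evaluation: solid rod, F = 4000 N, L = 0.4 m,
  ## r = 0.012 m -> sigma = (4000*0.1*0.012)/(pi*0.012^4/4) Pa
  expect_equal(long_bone_stress(4000, 0.4, 0.012),
               294.73137609610247, tolerance = 1e-10)
  expect_equal(long_bone_stress(0, 0.4, 0.012), 0)
  ## linear in the applied force
  expect_equal(long_bone_stress(8000, 0.4, 0.012),
               2 * long_bone_stress(4000, 0.4, 0.012))
  ## peak of a history is used
  expect_equal(long_bone_stress(c(100, 4000, 50), 0.4, 0.012),
               long_bone_stress(4000, 0.4, 0.012))
  expect_error(long_bone_stress(1, 0.4, 0.01, 0.02), "r_inner")
})

test_that("injury report flags follow the tolerance limits", {
  rep1 <- assess_injury(list(value = 3913, t1 = 0, t2 = 0.03),
                        chest_value = 50,
                        bone_stress = c(tibia = 389.5))
  cr <- rep1$criteria
  expect_true(cr$exceeded[cr$criterion == "HIC"])
  expect_true(cr$exceeded[cr$criterion == "tibia_stress_MPa"])
  expect_equal(cr$limit[cr$criterion == "HIC"], 1000)
  expect_equal(cr$limit[cr$criterion == "tibia_stress_MPa"], 124)
  ## boundary: just below both limits
  rep2 <- assess_injury(999.9, bone_stress = c(tibia = 123.9))
  expect_false(any(rep2$criteria$exceeded))
})

test_that("trace CSV readers accept resultant and 3-axis layouts", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = c(0, 0.001, 0.002),
                       resultant_g = c(0, 10, 0)), f, row.names = FALSE)
  tr <- read_trace_csv(f)
  expect_equal(tr$accel, c(0, 10, 0))
  write.csv(data.frame(time_s = c(0, 0.001), ax_g = c(3, 0),
                       ay_g = c(4, 0), az_g = c(0, 0)), f,
            row.names = FALSE)
  expect_equal(read_trace_csv(f)$accel, c(5, 0))
  unlink(f)
})
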