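test_that("inflow waveform: diastolic silence, peak amplitude, stroke volume", {
  Vh <- 5.6 * 1000 / 60
  t <- seq(0.5, 1 - 1e-6, length.out = 50)
  expect_equal(inflow_waveform(t, 0, 1, Vh), rep(0, 50))
  expect_equal(inflow_waveform(0.25, 0, 1, Vh), 4 * Vh, tolerance = 1e-12)
  # per-beat integral equals V_h (trapezoid on a fine grid)
  tt <- seq(0, 1, length.out = 2e5 + 1)
  q <- inflow_waveform(tt, 0, 1, Vh)
  integ <- sum(diff(tt) * (q[-1] + q[-length(q)]) / 2)
  expect_equal(integ / Vh, 1, tolerance = 1e-9)
  # doubling the rate doubles the peak at constant stroke volume
  expect_equal(inflow_waveform(0.125, 0, 2, Vh), 8 * Vh, tolerance = 1e-12)
})

test_that("constant inflow with fixed R/C settles on the resistive divider", {
  net <- network_params()
  ser <- backward_euler_run(net, 1, fixed_rc = list(R_S = 0.0155, C_S = 0.1),
                            inflow = "constant", Q_const = 93.33,
                            n_pre = 20)
  n <- nrow(ser)
  expect_equal(ser$P1[n], 93.33 * (0.1 + 0.0155 + 1), tolerance = 1e-6)
  expect_equal(ser$PS[n], 93.33 * (0.0155 + 1), tolerance = 1e-6)
  expect_equal(ser$P3[n], 93.33 * 1, tolerance = 1e-6)
  expect_equal(ser$QSp[n], ser$QSm[n], tolerance = 1e-6)
  expect_equal(ser$qS[n], 93.33, tolerance = 1e-6)
})

test_that("backward Euler converges under step refinement", {
  net <- network_params()
  rc <- list(R_S = 0.0155, C_S = 0.15)
  coarse <- backward_euler_run(net, 1, fixed_rc = rc, steps_per_beat = 200)
  fine <- backward_euler_run(net, 1, fixed_rc = rc, steps_per_beat = 2000)
  expect_lt(abs(max(coarse$PS) / max(fine$PS) - 1), 0.005)
})

test_that("pre-beats give a periodic physical window", {
  net <- network_params()
  rc <- list(R_S = 0.0155, C_S = 0.15)
  ser <- backward_euler_run(net, 1, fixed_rc = rc)
  spb <- net$steps_per_beat
  pk <- vapply(1:3, function(b)
    max(ser$PS[((b - 1) * spb + 1):(b * spb)]), 0)
  expect_lt(max(abs(pk / pk[1] - 1)), 0.001)
})

test_that("Poiseuille shear stress formula and scaling", {
  expect_equal(wall_shear_series(93.33, 6.2, 3.5e-3), 1.745, tolerance = 1e-3)
  expect_equal(wall_shear_series(0, 6.2, 3.5e-3), 0)
  expect_equal(wall_shear_series(5, 6.2, 3.5e-3) /
                 wall_shear_series(5, 12.4, 3.5e-3), 8, tolerance = 1e-12)
})

test_that("TAWSS trapezoidal average", {
  t <- seq(0, 3, length.out = 601)
  expect_equal(tawss(rep(1.6, 601), t), 1.6, tolerance = 1e-12)
  tau <- 2 + sin(2 * pi * t)  # whole periods: average 2
  expect_equal(tawss(tau, t), 2, tolerance = 1e-4)
  expect_error(tawss(1, 0), "window")
})

test_that("Poiseuille resistance matches the classical form", {
  A <- pi * 6^2
  expect_equal(poiseuille_resistance(A, 300, 3.5e-3), 0.0155,
               tolerance = 1e-2)
  # 8 pi mu l / A^2 is identical to 8 mu l / (pi r^4)
  r <- sqrt(A / pi)
  classical <- 8 * 3.5e-3 * 0.3 / (pi * (r * 1e-3)^4) / 133.322e6
  expect_equal(poiseuille_resistance(A, 300, 3.5e-3), classical,
               tolerance = 1e-12)
  expect_equal(poiseuille_resistance(2 * A, 300, 3.5e-3) /
                 poiseuille_resistance(A, 300, 3.5e-3), 0.25,
               tolerance = 1e-12)
})

test_that("raising downstream resistance raises the segment pressure", {
  net1 <- network_params(R3 = 1)
  net2 <- network_params(R3 = 1.5)
  rc <- list(R_S = 0.0155, C_S = 0.15)
  s1 <- backward_euler_run(net1, 1, fixed_rc = rc)
  s2 <- backward_euler_run(net2, 1, fixed_rc = rc)
  expect_gt(mean(s2$pS), mean(s1$pS))
})

test_that("mean segment quantities recompute from the stored series", {
  net <- network_params()
  ser <- backward_euler_run(net, 1, fixed_rc = list(R_S = 0.0155, C_S = 0.15))
  mq <- mean_segment_quantities(ser)
  expect_equal(mq$p_S, (ser$PS + ser$P3) / 2)
  expect_equal(mq$q_S, (ser$QSp + ser$QSm) / 2)
  expect_equal(mq$p_S, ser$pS, tolerance = 1e-12)
})
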