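# Flux readouts: anchoring, basal/amplitude/slope estimation, inversion.

mk_trace <- function(t, r, fr = 1) ratio_trace(t, r, fr)

test_that("anchoring zeroes the anchor window and is idempotent", {
  prot <- protocol_preset("mct_block")
  t <- seq(0, 420, by = 1)
  r <- 1.1 + 0.0002 * t
  tr <- mk_trace(t, r)
  for (kind in c("end_zero", "baseline")) {
    nt <- anchor_normalize(tr, prot, kind)
    w <- attr(nt, "window")
    expect_equal(mean(nt$dr[nt$t >= w[1] & nt$t <= w[2]]), 0, tolerance = 1e-12)
    twice <- anchor_normalize(nt, prot, kind)
    expect_equal(twice$dr, nt$dr, tolerance = 1e-12)
  }
  # constant trace normalizes to exactly zero
  flat <- anchor_normalize(mk_trace(t, rep(1.2, length(t))), prot, "baseline")
  expect_true(all(flat$dr == 0))
  # anchor window overlapping an onset is rejected
  expect_error(anchor_normalize(mk_trace(seq(0, 125, 1), rep(1.2, 126)),
                                prot, "end_zero"), "overlap")
})

test_that("basal is the baseline-window mean of the end-zero trace", {
  prot <- protocol_preset("trans_acceleration")
  t <- seq(0, 1320, by = 1)
  r <- ifelse(t < 120, 1.20, 1.0 + 0.20 * exp(-(t - 120) / 30))
  nt <- anchor_normalize(mk_trace(t, r), prot, "end_zero")
  est <- estimate_basal(nt, prot)
  expect_equal(est$basal, 0.20, tolerance = 1e-6)
  expect_length(est$flags, 0)
  # injected baseline drift raises the flag
  r_drift <- r + ifelse(t < 120, 0.05 * (t - 120) / 60, 0)
  nt2 <- anchor_normalize(mk_trace(t, r_drift), prot, "end_zero")
  expect_true("unstable_baseline" %in% estimate_basal(nt2, prot)$flags)
})

test_that("amplitude is the plateau mean and saturation is flagged", {
  prot <- protocol_preset("mct_block")
  t <- seq(0, 420, by = 1)
  r <- ifelse(t < 120, 1.0, ifelse(t < 200, 1.0 + 0.5 * (t - 120) / 80, 1.5))
  nt <- anchor_normalize(mk_trace(t, r), prot, "baseline")
  est <- estimate_amplitude(nt, prot)
  expect_equal(est$amplitude, 0.5, tolerance = 1e-9)
  # plateau ratio of 1.5 exceeds 95% of a 1.0..1.3 sensor range
  est2 <- estimate_amplitude(nt, prot, sensor = laconic_sensor())
  expect_true("saturation" %in% est2$flags)
})

test_that("slope fitting is exact on a line and first-order on an exponential", {
  prot <- protocol_preset("mct_block")
  t <- seq(0, 420, by = 0.5)
  dr <- pmax(0, 0.01 * (t - 120))
  nt <- anchor_normalize(mk_trace(t, 1 + dr), prot, "baseline")
  est <- estimate_slope(nt, prot, analysis_config(slope_delay_s = 0))
  expect_equal(est$slope, 0.6, tolerance = 1e-9)   # 0.01/s = 0.6/min
  expect_equal(est$r2, 1, tolerance = 1e-9)
  # A(1 - exp(-t/tau)) fitted over tau/10 stays within 5% of A/tau
  tau <- 100; A <- 0.3
  dr2 <- ifelse(t < 120, 0, A * (1 - exp(-(t - 120) / tau)))
  nt2 <- anchor_normalize(mk_trace(t, 1 + dr2), prot, "baseline")
  est2 <- estimate_slope(nt2, prot,
                         analysis_config(slope_delay_s = 0,
                                         slope_duration_s = tau / 10))
  expect_equal(est2$slope, A / tau * 60, tolerance = 0.05)
  # window validation
  expect_error(estimate_slope(nt, prot, analysis_config(slope_duration_s = 1e4)),
               "exceeds")
  short <- anchor_normalize(mk_trace(seq(0, 420, 30), rep(1.1, 15)), prot,
                            "baseline")
  expect_error(estimate_slope(short, prot), "fewer than 5")
})

test_that("readouts scale linearly with the trace", {
  prot <- protocol_preset("mct_block")
  t <- seq(0, 420, by = 1)
  set.seed(11)
  r <- 1.1 + 0.0003 * pmax(0, t - 120) + rnorm(length(t), 0, 0.002)
  nt1 <- anchor_normalize(mk_trace(t, r), prot, "baseline")
  a1 <- estimate_amplitude(nt1, prot); s1 <- estimate_slope(nt1, prot)
  sc <- 2.5
  nt3 <- nt1; nt3$dr <- nt1$dr * sc
  a3 <- estimate_amplitude(nt3, prot); s3 <- estimate_slope(nt3, prot)
  expect_equal(a3$amplitude, sc * a1$amplitude, tolerance = 1e-12)
  expect_equal(s3$slope, sc * s1$slope, tolerance = 1e-12)
})

test_that("simulated trans-acceleration basal matches sensor truth", {
  p <- kinetic_params()
  s <- laconic_sensor()
  prot <- protocol_preset("trans_acceleration")
  ser <- simulate_concentrations(p, prot, dt = 1)
  tr <- mk_trace(ser$t, sensor_forward(ser$lac_in, s))
  nt <- anchor_normalize(tr, prot, "end_zero")
  basal_truth <- sensor_forward(steady_state(p)[["lac_in"]], s) -
    sensor_forward(tail(ser$lac_in, 1), s)
  expect_equal(nt$dr[1], basal_truth, tolerance = 1e-4)
  est <- estimate_basal(nt, prot)
  expect_equal(est$basal, basal_truth, tolerance = 1e-3)
})

test_that("concentration inversion undoes the sensor mapping", {
  s <- laconic_sensor()
  prot <- protocol_preset("trans_acceleration")
  # anchored at r_min, basal at mid-range: inverted basal must be kd
  est <- fretflux:::flux_estimate(basal = (s$r_min + s$r_max) / 2 - s$r_min)
  inv <- invert_to_concentration(est, s$r_min, s)
  expect_equal(inv$basal, s$kd, tolerance = 1e-9)
  expect_identical(inv$units, "mM")
  # noiseless simulator round trip within 2%
  p <- kinetic_params()
  ser <- simulate_concentrations(p, prot, dt = 1)
  tr <- mk_trace(ser$t, sensor_forward(ser$lac_in, s))
  nt <- anchor_normalize(tr, prot, "end_zero")
  est2 <- estimate_basal(nt, prot)
  inv2 <- invert_to_concentration(est2, attr(nt, "anchor_value"), s)
  expect_equal(inv2$basal, steady_state(p)[["lac_in"]], tolerance = 0.02)
  # saturated plateau cannot be inverted
  est3 <- fretflux:::flux_estimate(amplitude = s$r_max - s$r_min + 0.1)
  expect_error(invert_to_concentration(est3, s$r_min, s), "out of sensor range")
})

test_that("analyze_trace maps protocols to their defined readouts", {
  p <- kinetic_params()
  s <- laconic_sensor()
  ser <- simulate_concentrations(p, protocol_preset("mct_block"), dt = 1)
  tr <- mk_trace(ser$t, sensor_forward(ser$lac_in, s))
  est <- analyze_trace(tr, "mct_block")
  expect_true(is.finite(est$amplitude) && is.finite(est$slope))
  expect_true(is.na(est$basal))
  ser2 <- simulate_concentrations(p, protocol_preset("trans_acceleration"), dt = 2)
  tr2 <- mk_trace(ser2$t, sensor_forward(ser2$lac_in, s))
  est2 <- analyze_trace(tr2, "trans_acceleration")
  expect_true(is.finite(est2$basal))
  expect_true(is.na(est2$slope) && is.na(est2$amplitude))
})
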