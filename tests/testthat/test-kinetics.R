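# Carrier-kinetics simulator: conservation, closed-form limits, protocol
# behaviour, and the structural bias properties of the transport model.

test_that("with all fluxes zero the concentrations are exactly conserved", {
  ser <- flat_series(lac = 1, glc = 2, duration = 20, dt = 1)
  expect_true(all(ser$lac_in == 1))
  expect_true(all(ser$glc_in == 2))
})

test_that("linearized efflux reaches the closed-form steady state p/k", {
  # small-concentration regime: lac << mct_km so efflux ~ (mct_vmax/mct_km) * lac;
  # hexokinase saturated (glc >> k_hk_km) so production is constant.
  p <- kinetic_params(j_hk_vmax = 0.002, k_hk_km = 1e-4,
                      glut_vmax = 0.05, glut_km = 3,
                      lac_prod_frac = 1, mct_vmax = 1, mct_km = 1000)
  k <- p$mct_vmax / p$mct_km          # 1e-3 per s; lac/mct_km stays < 0.3%
  prod <- p$lac_prod_frac * p$j_hk_vmax
  t_settle <- 10 / k
  prot <- protocol("settle", list(protocol_event("BASELINE", 0)), t_settle)
  ser <- simulate_concentrations(p, prot, dt = t_settle / 100,
                                 init = c(steady_state(p)[["glc_in"]], 0))
  # closed form of dL/dt = p - kL from L(0)=0: L(t) = (p/k)(1 - exp(-kt))
  expect_equal(tail(ser$lac_in, 1), prod / k * (1 - exp(-k * t_settle)),
               tolerance = 0.01)
  # also pointwise along the approach (linear-limit agreement)
  expect_equal(ser$lac_in,
               prod / k * (1 - exp(-k * ser$t)), tolerance = 0.01)
})

test_that("full MCT block turns lactate into a ramp at the production flux", {
  p <- kinetic_params(mct4_frac = 0)
  prot <- protocol_preset("mct_block")
  ser <- simulate_concentrations(p, prot, dt = 1)
  post <- ser$t >= 130 & ser$t <= 250
  dl <- diff(ser$lac_in[post])           # per 1 s
  g <- ser$glc_in[post]
  prod <- p$lac_prod_frac * p$j_hk_vmax * g / (p$k_hk_km + g)
  expect_equal(dl, prod[-length(prod)] * 1, tolerance = 1e-3)
  # slope of the ramp equals production to high accuracy
  expect_equal(mean(dl), mean(prod), tolerance = 1e-3)
})

test_that("oxamate depletion and aglycemia drive lactate to the same floor", {
  p <- kinetic_params()
  end_ox <- tail(simulate_concentrations(
    p, protocol_preset("trans_acceleration"), dt = 5)$lac_in, 1)
  end_ag <- tail(simulate_concentrations(
    p, protocol_preset("aglycemia_only"), dt = 5)$lac_in, 1)
  basal <- steady_state(p)[["lac_in"]]
  expect_lt(abs(end_ox - end_ag), 0.05 * basal)
})

test_that("invalid inputs are rejected", {
  expect_error(kinetic_params(mct_vmax = -1), "mct_vmax")
  expect_error(kinetic_params(mct4_frac = 1.5), "mct4_frac")
  expect_error(kinetic_params(lac_prod_frac = 2.5), "lac_prod_frac")
  expect_error(simulate_concentrations(kinetic_params(),
                                       protocol_preset("mct_block"),
                                       dt = 1000), "duration")
  expect_error(protocol("bad", list(protocol_event("OXAMATE_ON", 0)), 10),
               "BASELINE")
  expect_error(protocol("bad", list(protocol_event("BASELINE", 0),
                                    protocol_event("ARC_ON", 0)), 10),
               "increasing")
})

test_that("concentrations stay nonnegative across random admissible models", {
  set.seed(401)
  for (i in 1:12) {
    p <- kinetic_params(
      j_hk_vmax = runif(1, 0, 0.03), k_hk_km = runif(1, 0.02, 2),
      glut_vmax = runif(1, 0.01, 0.2), glut_km = runif(1, 0.5, 8),
      lac_prod_frac = runif(1, 0, 2),
      mct_vmax = 0.15 + runif(1, 0, 0.1),   # keeps efflux able to balance
      mct_km = runif(1, 0.5, 8),
      trans_accel_gain = runif(1, 0, 60), mct4_frac = runif(1, 0, 1))
    prot <- protocol_preset(sample(c("trans_acceleration", "mct_block",
                                     "glut_block_then_aglycemia",
                                     "aglycemia_only"), 1))
    ser <- simulate_concentrations(p, prot, dt = 10)
    expect_true(all(ser$lac_in >= 0) && all(ser$glc_in >= 0))
  }
})

test_that("basal lactate and post-block ramp are monotone in production fraction", {
  fr <- c(0.4, 0.8, 1.2, 1.6, 2.0)
  basal <- vapply(fr, function(f)
    steady_state(kinetic_params(lac_prod_frac = f))[["lac_in"]], numeric(1))
  expect_true(all(diff(basal) > 0))
  prot <- protocol_preset("mct_block")
  ramp <- vapply(fr, function(f) {
    ser <- simulate_concentrations(kinetic_params(lac_prod_frac = f), prot, dt = 5)
    post <- ser$t >= 130 & ser$t <= 250
    unname(coef(lm(ser$lac_in[post] ~ ser$t[post]))[2])
  }, numeric(1))
  expect_true(all(diff(ramp) > 0))
})

test_that("MCT4 escape makes the post-block ramp undershoot true production", {
  prot <- protocol_preset("mct_block")
  fr <- c(0, 0.2, 0.4, 0.6)
  deficit <- vapply(fr, function(m4) {
    p <- kinetic_params(mct4_frac = m4)
    ser <- simulate_concentrations(p, prot, dt = 2)
    post <- ser$t >= 130 & ser$t <= 250
    g <- mean(ser$glc_in[post])
    prod <- p$lac_prod_frac * p$j_hk_vmax * g / (p$k_hk_km + g)
    slope <- unname(coef(lm(ser$lac_in[post] ~ ser$t[post]))[2])
    prod - slope
  }, numeric(1))
  expect_gt(deficit[2], 0)                # any escape biases the ramp down
  expect_true(all(diff(deficit) > 0))     # deficit grows with mct4_frac
})

test_that("steady state balances the model fluxes", {
  p <- kinetic_params()
  ss <- steady_state(p)
  prot <- flat_protocol(200)
  ser <- simulate_concentrations(p, prot, dt = 10,
                                 init = c(ss[["glc_in"]], ss[["lac_in"]]))
  expect_equal(tail(ser$lac_in, 1), ss[["lac_in"]], tolerance = 1e-6)
  expect_equal(tail(ser$glc_in, 1), ss[["glc_in"]], tolerance = 1e-6)
})
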