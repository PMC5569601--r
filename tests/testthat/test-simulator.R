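test_that("brake-free emptying matches the exact exponential", {
  g0 <- 9.23e-4
  cfg <- exp_config(N0 = 20.82, gamma0 = g0, t_final = 2 * log(2) / g0,
                    dt = 0.1)
  tr <- simulate(cfg, keep_field = FALSE)
  t_half <- log(2) / g0
  sim <- approx(tr$time_s, tr$nutrient_g, xout = t_half)$y
  expect_equal(sim, 20.82 * exp(-g0 * t_half), tolerance = 0.01)
  expect_equal(half_time(tr, "nutrient"), t_half, tolerance = 0.01)
})

test_that("a zero-mass meal yields an identically zero trajectory", {
  cfg <- exp_config(N0 = 0, gamma0 = 1e-3, Ka = 1e-3, t_final = 600)
  tr <- simulate(cfg)
  expect_true(all(tr$nutrient_g == 0))
  expect_true(all(tr$absorption_g_s == 0))
  expect_true(all(tr$cum_absorbed_g == 0))
  expect_true(is.na(half_time(tr, "nutrient")))
})

test_that("the compiled march equals the composition of R-level operations", {
  cfg <- simulation_config(
    meal = meal_spec(nutrient_mass_0 = 30, liquid_mass_0 = 400,
                     thickener_mass_0 = 5),
    hypothesis = emptying_hypothesis("SEC_PLUS_C", m_sec = 0.0025,
                                     C1 = 6.58e-4),
    feedback = feedback_params(A_max = 5e-3),
    secretion = secretion_params(0.018, 1.5, 0.018),
    K_a = 2e-3, t_final = 1, record_every = 1L)
  dt <- 20
  n <- 40
  cfg$dt <- dt
  cfg$t_final <- n * dt
  tr <- simulate(cfg, keep_field = FALSE)
  or <- r_oracle_march(cfg, n, dt)
  expect_equal(tr$nutrient_g, or$nutrient_g, tolerance = 1e-12)
  expect_equal(tr$liquid_g, or$liquid_g, tolerance = 1e-12)
  expect_equal(tr$absorption_g_s, or$absorption_g_s, tolerance = 1e-12)
  expect_equal(tr$cum_absorbed_g, or$cum_absorbed_g, tolerance = 1e-12)
  expect_equal(tr$cum_outflow_g, or$cum_outflow_g, tolerance = 1e-12)
})

test_that("nutrient is conserved across compartments at all output times", {
  for (cond in c("a", "b", "d", "e", "g")) {
    cfg <- preset_feedback(cond, t_final = 7200)
    tr <- simulate(cfg)
    n0 <- cfg$meal$nutrient_mass_0
    recon <- tr$nutrient_g + tr$intestine_g + tr$cum_absorbed_g +
      tr$cum_outflow_g
    expect_true(all(abs(recon - n0) / n0 < 1e-3))
    expect_lt(attr(tr, "mass_balance_rel_err"), 1e-10)
    expect_true(all(diff(tr$cum_absorbed_g) >= 0))
    expect_true(all(diff(tr$cum_outflow_g) >= 0))
  }
})

test_that("the 20 g condition is near-critical around 15 min", {
  cfg <- preset_feedback("b", t_final = 7200)
  tr <- simulate(cfg)
  peak <- which.max(tr$absorption_g_s)
  expect_gt(max(tr$absorption_g_s), 0.95 * cfg$feedback$A_max)
  expect_gt(tr$time_s[peak] / 60, 10)
  expect_lt(tr$time_s[peak] / 60, 25)
  # any brake engagement must be confined to that window
  on <- tr$time_s[tr$gamma_per_s == 0]
  if (length(on)) expect_true(all(on / 60 > 10 & on / 60 < 25))
})

test_that("high loads empty linearly under the brake, low loads exponentially", {
  trd <- simulate(preset_feedback("d", t_final = 14400))
  on <- range(trd$time_s[trd$gamma_per_s == 0])
  seg <- trd[trd$time_s >= on[1] & trd$time_s <= on[2], ]
  expect_gt(summary(lm(nutrient_g ~ time_s, seg))$r.squared, 0.98)
  tra <- simulate(preset_feedback("a", t_final = 7200))
  sega <- tra[tra$nutrient_g > 1e-3 * tra$nutrient_g[1], ]
  expect_gt(summary(lm(log(nutrient_g) ~ time_s, sega))$r.squared, 0.99)
})

test_that("half-times behave as closed form, order and sentinel demand", {
  g0 <- 1e-3
  tr <- simulate(exp_config(N0 = 10, gamma0 = g0, t_final = 3600))
  expect_equal(half_time(tr, "nutrient"), log(2) / g0,
               tolerance = attr(tr, "dt_used") / (log(2) / g0))
  # secretions swell the total content: nutrient half-time comes first
  trh <- simulate(preset_meal("HVN", t_final = 7200), keep_field = FALSE)
  expect_lt(half_time(trh, "nutrient"), half_time(trh, "total"))
  # constant series never crosses
  cfg0 <- exp_config(N0 = 5, gamma0 = 1e-9, t_final = 600)
  expect_true(is.na(half_time(simulate(cfg0), "nutrient")))
})

test_that("mean caloric delivery matches the brake ceiling and bookkeeping", {
  cfg <- preset_feedback("d", t_final = 14400)
  tr <- simulate(cfg)
  on <- range(tr$time_s[tr$gamma_per_s == 0])
  expect_equal(caloric_delivery_rate(tr, on[1], on[2]), cfg$feedback$A_max,
               tolerance = 0.05)
  # internal consistency with the cumulative absorbed series
  whole <- caloric_delivery_rate(tr, 0, max(tr$time_s))
  expect_equal(whole, max(tr$cum_absorbed_g) / max(tr$time_s),
               tolerance = 0.01)
  expect_error(caloric_delivery_rate(tr, 100, 100),
               class = "gastrosim_domain_error")
})

test_that("secretion swells high-viscosity meals before they empty", {
  # cumulative secretion strictly increasing in initial viscosity,
  # half-times nearly invariant
  res <- vapply(c(0.06, 2, 5.6, 11), function(mu0) {
    tr <- simulate(nonnutrient_config(mu0, t_final = 3600), keep_field = FALSE)
    mu30 <- approx(tr$time_s, tr$viscosity_pa_s, xout = 1800)$y
    c(half = half_time(tr, "total"), sec = max(tr$cum_secreted_g),
      drop = 1 - mu30 / mu0)
  }, numeric(3))
  expect_true(all(diff(res["sec", ]) > 0))
  expect_true(all(diff(res["drop", ]) > 0))
  spread <- diff(range(res["half", ])) / mean(res["half", ])
  expect_lt(spread, 0.15)
})

test_that("glucose half-time is non-decreasing in load for both meal types", {
  for (m in c("LVN", "HVN")) {
    th <- vapply(c(20, 40, 80), function(g) {
      half_time(simulate(preset_meal(m, nutrient_mass_0 = g,
                                     t_final = 14400), keep_field = FALSE),
                "nutrient")
    }, numeric(1))
    expect_true(all(diff(th) >= -1e-9))
  }
})

test_that("instability is caught and dt auto-refined", {
  cfg <- exp_config(N0 = 10, gamma0 = 1e-3, t_final = 600)
  cfg$dt <- 2000  # violates the transport CFL outright
  expect_error(simulate(cfg), class = "gastrosim_stability_error")
  # a gastric-unstable dt (gamma*dt > 1) is refined, not fatal
  cfg2 <- exp_config(N0 = 10, gamma0 = 0.5, t_final = 60, dz = 2.85 / 57)
  tr <- simulate(cfg2)
  expect_lt(attr(tr, "dt_used") * 0.5, 1)
  expect_true(all(tr$nutrient_g >= 0))
})
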