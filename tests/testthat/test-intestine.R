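test_that("bolus injection is exact, linear and trapezoid-consistent", {
  f <- intestine_field(L = 1, dz = 0.01, K_a = 0.1, l_0 = 0.025)
  expect_identical(inject_bolus(f, 0)$densities, f$densities)
  f1 <- inject_bolus(f, 1)
  expect_equal(max(f1$densities), 100)
  expect_equal(sum(f1$densities > 0), 1)
  expect_equal(intestine_mass(f1), 1)
  # two injections of 0.5 g equal one of 1 g
  f2 <- inject_bolus(inject_bolus(f, 0.5), 0.5)
  expect_identical(f2$densities, f1$densities)
})

test_that("pure absorption decays as the scheme's exact geometric factor", {
  f <- intestine_field(L = 1, dz = 0.01, u_bar = 0, K_a = 0.05, l_0 = 0.3)
  f <- inject_bolus(f, 2)
  dt <- 0.5
  for (i in 1:40) f <- step_transport(f, dt)$field
  expect_equal(intestine_mass(f), 2 * (1 - 0.05 * dt)^40, tolerance = 1e-12)
  # and approaches exp(-k t) as dt -> 0
  f2 <- intestine_field(L = 1, dz = 0.01, u_bar = 0, K_a = 0.05, l_0 = 0.3)
  f2 <- inject_bolus(f2, 2)
  for (i in 1:2000) f2 <- step_transport(f2, 0.01)$field
  expect_equal(intestine_mass(f2), 2 * exp(-0.05 * 20), tolerance = 1e-3)
})

test_that("pure advection conserves mass to machine precision", {
  f <- intestine_field(L = 0.5, dz = 0.005, u_bar = 1e-3, K_a = 0, l_0 = 0.05)
  f <- inject_bolus(f, 3)
  dt <- 0.9 * f$dz / f$u_bar
  total_out <- 0
  for (i in 1:300) {
    st <- step_transport(f, dt)
    f <- st$field
    total_out <- total_out + st$outflow
    expect_identical(st$absorbed, 0)
  }
  expect_equal(intestine_mass(f) + total_out, 3, tolerance = 1e-12)
})

test_that("per-step mass balance is exact under random injections", {
  set.seed(42)
  f <- intestine_field(L = 1, dz = 0.02, u_bar = 5e-4, K_a = 0.002, l_0 = 0.1)
  dt <- 0.8 / (f$u_bar / f$dz + f$K_a)
  for (i in 1:100) {
    inflow <- runif(1, 0, 0.5)
    f <- inject_bolus(f, inflow)
    m_before <- intestine_mass(f) # post-injection
    st <- step_transport(f, dt)
    expect_equal(intestine_mass(st$field),
                 m_before - st$absorbed - st$outflow,
                 tolerance = 1e-10)
    expect_true(all(st$field$densities >= 0))
    f <- st$field
  }
})

test_that("stability violations abort with the admissible dt", {
  f <- intestine_field(L = 1, dz = 0.01, u_bar = 1e-3, K_a = 0.05, l_0 = 0.1)
  err <- expect_error(step_transport(f, 100), class = "gastrosim_stability_error")
  expect_match(conditionMessage(err), "dt must be <=")
})

test_that("absorption rate integrates the reactive term", {
  f <- intestine_field(L = 2, dz = 0.01, K_a = 0.03, l_0 = 0.4)
  expect_identical(absorption_rate(f), 0)
  # uniform density d over [0, L]: A = k d L (trapezoid exact for constants)
  f$densities[] <- 5
  expect_equal(absorption_rate(f), 0.03 * 5 * 2)
  # single-node bolus of mass m: A = k m independent of dz
  for (dz in c(0.01, 0.004)) {
    g <- inject_bolus(intestine_field(L = 2, dz = dz, K_a = 0.03, l_0 = 0.4), 1.7)
    expect_equal(absorption_rate(g), 0.03 * 1.7)
  }
})

test_that("halving dz and dt changes cumulative absorption by < 1%", {
  base <- preset_feedback("b", t_final = 3600)
  tr1 <- simulate(base, keep_field = FALSE)
  fine <- base
  fine$dz <- base$dz / 2
  fine$dt <- attr(tr1, "dt_used") / 2
  tr2 <- simulate(fine, keep_field = FALSE)
  a1 <- max(tr1$cum_absorbed_g)
  a2 <- max(tr2$cum_absorbed_g)
  expect_lt(abs(a1 - a2) / a2, 0.01)
})
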