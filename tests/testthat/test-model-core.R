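test_that("power-law rheology reproduces the anchor viscosities", {
  rh <- rheology_params()
  expect_identical(viscosity_from_concentration(0, rh), 0)
  expect_equal(viscosity_from_concentration(1, rh), 2)
  # 2 * 1.5^4.21
  expect_equal(viscosity_from_concentration(1.5, rh), 2 * 1.5^4.21)
  expect_equal(viscosity_from_concentration(1.5, rh), 11.02, tolerance = 1e-3)
  expect_error(viscosity_from_concentration(-1, rh),
               class = "gastrosim_domain_error")
})

test_that("concentration follows dilution and rejects degenerate states", {
  expect_equal(concentration_from_state(1.5, 100), 1.5)
  expect_equal(concentration_from_state(0, 100), 0)
  expect_equal(concentration_from_state(1.5, 200), 0.75)
  expect_error(concentration_from_state(1.5, 0),
               class = "gastrosim_degenerate_state")
})

test_that("secretion rate has the basal limit and scales with viscosity", {
  p <- secretion_params(lambda_s = 0.018, b = 1.5, S_b = 0.018)
  expect_equal(secretion_rate(0, p), 0.018)
  expect_equal(secretion_rate(1, p), 0.036)
  expect_equal(secretion_rate(4, p), 0.018 * 8 + 0.018)
  expect_error(secretion_rate(-0.1, p), class = "gastrosim_domain_error")
})

test_that("rheology and secretion laws are monotone on a grid", {
  grid <- seq(0, 12, length.out = 100)
  mu <- viscosity_from_concentration(seq(0, 3, length.out = 100))
  expect_true(all(diff(mu) > 0))
  ks <- secretion_rate(grid)
  expect_true(all(diff(ks) >= 0))
})

test_that("emptying hypotheses evaluate their prescribed combinations", {
  h <- emptying_hypothesis("SEC_PLUS_C", m_sec = 0.0025, C1 = 6.58e-4)
  expect_equal(gamma0(h, K_sec = 0.018), 0.0025 * 0.018 + 6.58e-4)
  expect_equal(gamma0(h, K_sec = 0.018), 7.03e-4, tolerance = 1e-3)
  expect_equal(gamma0(h, K_sec = 0), 6.58e-4)
  h2 <- emptying_hypothesis("VISC_PLUS_C", m_mu = 0, C1 = 1e-3)
  expect_equal(gamma0(h2, mu = 50), 1e-3)
  expect_error(emptying_hypothesis("SEC_PLUS_C", m_mu = 1, C1 = 1),
               class = "gastrosim_config_error")
})

test_that("gamma0 is linear in each hypothesis constant", {
  h1 <- emptying_hypothesis("VISC_PLUS_VOL", m_mu = 0.01, m_s = 2)
  h2 <- emptying_hypothesis("VISC_PLUS_VOL", m_mu = 0.02, m_s = 2)
  mu <- 3; V <- 5e-4
  # doubling m_mu doubles the viscosity term's contribution
  expect_equal(gamma0(h2, mu = mu, V_tot = V) - gamma0(h1, mu = mu, V_tot = V),
               0.01 * mu)
  h3 <- emptying_hypothesis("SEC_PLUS_VOL", m_sec = 0.001, m_s = 2)
  h4 <- emptying_hypothesis("SEC_PLUS_VOL", m_sec = 0.002, m_s = 2)
  expect_equal(gamma0(h4, K_sec = 0.5, V_tot = V) - gamma0(h3, K_sec = 0.5, V_tot = V),
               0.001 * 0.5)
})

test_that("the brake switch has the exact midpoint, limits and guard", {
  fb_s <- feedback_params(A_max = 0.01, mode = "smooth")
  fb_l <- feedback_params(A_max = 0.01, mode = "logical")
  g0 <- 1e-3
  expect_equal(effective_gamma(0.01, g0, fb_s), g0 / 2)
  expect_equal(effective_gamma(0, g0, fb_l), g0)
  expect_equal(effective_gamma(0.02, g0, fb_l), 0)
  # saturation far beyond the threshold
  expect_lt(effective_gamma(0.01 + 100 / fb_s$tau_A, g0, fb_s), 1e-4 * g0)
  # overflow guard returns the exact limits
  expect_identical(effective_gamma(1e9, g0, fb_s), 0)
  expect_identical(effective_gamma(0, g0, feedback_params(A_max = 1e9, mode = "smooth")),
                   g0)
  expect_identical(effective_gamma(0.5, g0, feedback_params(A_max = Inf)), g0)
})

test_that("smooth switch converges to the logical switch at tau_A = 5e6", {
  g0 <- 1e-3
  fb_s <- feedback_params(A_max = 0.01, tau_A = 5e6, mode = "smooth")
  fb_l <- feedback_params(A_max = 0.01, mode = "logical")
  A <- seq(0, 0.02, length.out = 2001)
  d <- abs(effective_gamma(A, g0, fb_s) - effective_gamma(A, g0, fb_l))
  # they differ only within a 1e-5 g/s collar of the threshold
  expect_true(all(d[abs(A - 0.01) >= 1e-5] < 1e-9 * g0))
})
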