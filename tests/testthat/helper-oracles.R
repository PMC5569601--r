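# Independent reference implementations used as oracles.

# Coupled forward-Euler march composed from the package's elementary R-level
# operations (algebraic laws + intestine ops).  Independent of the compiled
# stepper; used to cross-check it step by step.
r_oracle_march <- function(cfg, n_steps, dt) {
  m <- cfg$meal
  field <- intestine_field(L = cfg$L, dz = cfg$dz, u_bar = cfg$u_bar,
                           K_a = cfg$K_a, l_0 = cfg$l_0)
  stomN <- m$nutrient_mass_0; liq <- m$liquid_mass_0
  lbg <- m$thickener_mass_0
  cum_abs <- 0; cum_out <- 0
  out <- data.frame(time_s = numeric(0), nutrient_g = numeric(0),
                    liquid_g = numeric(0), thickener_g = numeric(0),
                    absorption_g_s = numeric(0),
                    cum_absorbed_g = numeric(0), cum_outflow_g = numeric(0))
  for (k in 0:n_steps) {
    conc <- if (liq > 0) concentration_from_state(lbg, liq, cfg$rheology$rho_w) else 0
    mu <- viscosity_from_concentration(conc, cfg$rheology)
    Ksec <- if (is.null(cfg$secretion)) 0 else secretion_rate(mu, cfg$secretion)
    Vtot <- (stomN + liq + lbg) / cfg$rheology$rho_w * 1e-6
    g0 <- gamma0(cfg$hypothesis, mu = mu, V_tot = Vtot, K_sec = Ksec)
    A <- absorption_rate(field)
    g <- effective_gamma(A, g0, cfg$feedback)
    out <- rbind(out, data.frame(time_s = k * dt, nutrient_g = stomN,
                                 liquid_g = liq, thickener_g = lbg,
                                 absorption_g_s = A,
                                 cum_absorbed_g = cum_abs,
                                 cum_outflow_g = cum_out))
    if (k == n_steps) break
    emptied <- g * stomN * dt
    stomN <- stomN - emptied
    liq <- liq + dt * (Ksec - g * liq)
    lbg <- lbg - dt * g * lbg
    field <- inject_bolus(field, emptied)
    st <- step_transport(field, dt)
    field <- st$field
    cum_abs <- cum_abs + st$absorbed
    cum_out <- cum_out + st$outflow
  }
  out
}

# quick constructor for feedback-only configs used across tests
exp_config <- function(N0 = 20, gamma0 = 1e-3, Amax = Inf, Ka = 0,
                       t_final = 3600, ...) {
  simulation_config(
    meal = meal_spec(nutrient_mass_0 = N0, liquid_mass_0 = 500),
    hypothesis = constant_emptying(gamma0),
    feedback = feedback_params(A_max = Amax),
    K_a = Ka, t_final = t_final, ...)
}
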