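hyp_code <- function(form) {
  match(form, hypothesis_forms) - 1L  # CONSTANT = 0
}

hyp_const <- function(h, name) h[[name]] %||% 0

core_call <- function(config, dt, n_steps, every) {
  m <- config$meal; h <- config$hypothesis; fb <- config$feedback
  rh <- config$rheology; sec <- config$secretion
  simulate_core_cpp(
    stomN0 = m$nutrient_mass_0, liq0 = m$liquid_mass_0,
    lbg0 = m$thickener_mass_0,
    aL = rh$a_L, bL = rh$b_L, rho_w = rh$rho_w,
    has_secretion = !is.null(sec),
    lambda_s = if (is.null(sec)) 0 else sec$lambda_s,
    b_exp = if (is.null(sec)) 1 else sec$b,
    S_b = if (is.null(sec)) 0 else sec$S_b,
    hyp_form = hyp_code(h$form),
    m_mu = hyp_const(h, "m_mu"), m_s = hyp_const(h, "m_s"),
    m_sec = hyp_const(h, "m_sec"), C1 = hyp_const(h, "C1"),
    A_max = fb$A_max, tau_A = fb$tau_A,
    smooth_switch = fb$mode == "smooth",
    Ka = config$K_a, L = config$L, u_bar = config$u_bar,
    dz = config$dz, l0 = config$l_0,
    dt = dt, n_steps = n_steps, every = as.integer(every))
}

# lean march for objective functions: every step recorded, plain vectors,
# one halving retry pass, no tibble construction
sim_fast <- function(config, dt, t_final, max_refine = 12L) {
  for (attempt in 0:max_refine) {
    n_steps <- max(1L, as.integer(ceiling(t_final / dt)))
    res <- core_call(config, dt, n_steps, 1L)
    if (isTRUE(res$ok)) {
      res$dt <- dt
      return(res)
    }
    dt <- dt / 2
  }
  abort("simulation unstable at the smallest attempted dt",
        class = "gastrosim_stability_error")
}

#' Simulate the coupled gastric/intestinal model
#'
#' Marches the gastric compartment (nutrient, liquid, thickener), the
#' viscosity-driven secretion law and the 1-D intestinal transport forward
#' in time with an explicit Euler scheme.  Each step evaluates, in order:
#' concentration, viscosity, secretion rate, base emptying rate `gamma_0`,
#' the absorption rate `A` from the intestinal field of the previous step,
#' and the brake-gated rate `gamma`; then updates the gastric masses,
#' injects the emptied nutrient `gamma * StomN * dt` at `l_0`, and steps
#' the transport scheme.
#'
#' If the march produces a negative or non-finite state (an Euler stability
#' failure), `dt` is halved and the run restarted, up to `max_refine`
#' times; the step actually used is recorded in the result's `dt_used`
#' attribute.
#'
#' @param config A [simulation_config()].
#' @param keep_field Keep the final intestinal field in the `field`
#'   attribute (default `TRUE`).
#' @param max_refine Maximum number of automatic `dt` halvings.
#' @return A tibble of class `gastro_trajectory` with columns `time_s`,
#'   `nutrient_g`, `liquid_g`, `thickener_g`, `total_g`, `viscosity_pa_s`,
#'   `secretion_g_s`, `gamma0_per_s`, `gamma_per_s`, `absorption_g_s`,
#'   `cum_absorbed_g`, `cum_outflow_g`, `cum_secreted_g`, `intestine_g`,
#'   and attributes `config`, `dt_used`, `field`, `mass_balance_rel_err`.
#' @examples
#' cfg <- simulation_config(
#'   meal = meal_spec(nutrient_mass_0 = 20.82, liquid_mass_0 = 500),
#'   hypothesis = constant_emptying(9.23e-4),
#'   feedback = feedback_params(A_max = 7e-3),
#'   K_a = 9e-4, t_final = 7200
#' )
#' tr <- simulate(cfg)
#' half_time(tr, "nutrient") / 60  # minutes
#' @export
simulate <- function(config, keep_field = TRUE, max_refine = 12L) {
  stopifnot(inherits(config, "simulation_config"))
  m <- config$meal
  h <- config$hypothesis
  fb <- config$feedback
  rh <- config$rheology
  sec <- config$secretion

  dt_bound <- 1 / (config$u_bar / config$dz + config$K_a)
  dt <- config$dt %||% (0.9 * dt_bound)
  if (dt > dt_bound) {
    abort(sprintf("dt = %g s violates the transport stability bound; need dt <= %.6g s",
                  dt, dt_bound), class = "gastrosim_stability_error")
  }

  for (attempt in 0:max_refine) {
    n_steps <- max(1L, as.integer(ceiling(config$t_final / dt)))
    every <- config$record_every %||% max(1L, n_steps %/% 600L)
    n_steps <- as.integer(ceiling(n_steps / every) * every)
    res <- core_call(config, dt, n_steps, every)
    if (isTRUE(res$ok)) break
    if (attempt == max_refine) {
      abort(sprintf("simulation unstable (%s) even at dt = %g s", res$reason, dt),
            class = "gastrosim_stability_error")
    }
    dt <- dt / 2
  }

  k <- res$n_recorded
  idx <- seq_len(k)
  tr <- tibble(
    time_s = res$time_s[idx],
    nutrient_g = res$nutrient_g[idx],
    liquid_g = res$liquid_g[idx],
    thickener_g = res$thickener_g[idx],
    total_g = res$nutrient_g[idx] + res$liquid_g[idx] + res$thickener_g[idx],
    viscosity_pa_s = res$viscosity_pa_s[idx],
    secretion_g_s = res$secretion_g_s[idx],
    gamma0_per_s = res$gamma0_per_s[idx],
    gamma_per_s = res$gamma_per_s[idx],
    absorption_g_s = res$absorption_g_s[idx],
    cum_absorbed_g = res$cum_absorbed_g[idx],
    cum_outflow_g = res$cum_outflow_g[idx],
    cum_secreted_g = res$cum_secreted_g[idx]
  )
  # nutrient mass balance: stomach + lumen + absorbed + outflow = input
  tr$intestine_g <- m$nutrient_mass_0 - tr$nutrient_g -
    tr$cum_absorbed_g - tr$cum_outflow_g
  final_lumen <- sum(res$field) - 0.5 * (res$field[1] + res$field[length(res$field)])
  final_lumen <- final_lumen * config$dz
  bal_err <- if (m$nutrient_mass_0 > 0) {
    abs(tail(tr$intestine_g, 1) - final_lumen) / m$nutrient_mass_0
  } else 0

  structure(tr,
            class = c("gastro_trajectory", class(tr)),
            config = config, dt_used = dt,
            field = if (keep_field) res$field else NULL,
            mass_balance_rel_err = bal_err)
}

#' Gastric half-emptying time
#'
#' First time the chosen gastric series falls to half its initial value,
#' linearly interpolated between recorded steps.
#'
#' @param trajectory A `gastro_trajectory` from [simulate()].
#' @param which `"total"` (total gastric content, as MRI would see) or
#'   `"nutrient"` (the labelled nutrient only, as scintigraphy would see).
#' @return Half-time in seconds, or `NA` if the series never crosses half
#'   its initial value within the horizon.
#' @export
half_time <- function(trajectory, which = c("total", "nutrient")) {
  which <- match.arg(which)
  y <- switch(which, total = trajectory$total_g, nutrient = trajectory$nutrient_g)
  t <- trajectory$time_s
  y0 <- y[1]
  if (y0 <= 0) return(NA_real_)
  target <- y0 / 2
  below <- which(y <= target)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(t[1])
  # linear interpolation on the bracketing interval
  t[i - 1] + (t[i] - t[i - 1]) * (y[i - 1] - target) / (y[i - 1] - y[i])
}

#' Mean caloric (nutrient) delivery rate to the gut
#'
#' Time-average of the absorption rate `A(t)` over a window, by the
#' trapezoidal rule on the recorded grid.
#'
#' @param trajectory A `gastro_trajectory`.
#' @param t1,t2 Window bounds in seconds (`t1 < t2`, inside the horizon).
#' @return Mean absorption rate, g/s.
#' @export
caloric_delivery_rate <- function(trajectory, t1, t2) {
  if (t2 <= t1) abort("need t1 < t2", class = "gastrosim_domain_error")
  t <- trajectory$time_s
  if (t1 < min(t) - 1e-9 || t2 > max(t) + 1e-9)
    abort("window outside the simulated horizon", class = "gastrosim_domain_error")
  keep <- t >= t1 & t <= t2
  tt <- t[keep]
  aa <- trajectory$absorption_g_s[keep]
  if (length(tt) < 2) abort("window contains fewer than two recorded points",
                            class = "gastrosim_domain_error")
  sum(diff(tt) * (head(aa, -1) + tail(aa, -1)) / 2) / (max(tt) - min(tt))
}

#' @export
print.gastro_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<gastro_trajectory> %d points over %.1f min (dt = %.3g s)\n",
              nrow(x), max(x$time_s) / 60, attr(x, "dt_used")))
  NextMethod()
}
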