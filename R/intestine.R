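#' Discretised intestinal nutrient field
#'
#' Nutrient linear density (g/m) on a uniform grid over the intestinal axis
#' `[0, L]`.  Flow is in +z with mean velocity `u_bar`; nutrient is absorbed
#' from the lumen at first-order rate `K_a`; boluses emptied from the
#' stomach enter at position `l_0`.  Zero-gradient (Neumann) conditions hold
#' at both ends; with upwind advection nothing propagates towards the
#' pylorus, so the inlet stays empty and mass bookkeeping is exact.
#'
#' @param L Intestinal length, m.
#' @param dz Grid spacing, m (must divide `L` into a whole number of cells).
#' @param u_bar Mean flow velocity, m/s.
#' @param K_a Absorption constant, 1/s.
#' @param l_0 Bolus injection position, m (`0 < l_0 < L`).
#' @return An object of class `intestine_field` with elements `densities`
#'   (length `L/dz + 1`), `z_nodes`, `dz`, `L`, `u_bar`, `K_a`, `l_0`.
#' @export
intestine_field <- function(L = 2.85, dz = L / 570, u_bar = 1.7e-4,
                            K_a = 0, l_0 = 0.025) {
  if (dz <= 0 || L <= 0 || l_0 <= 0 || l_0 >= L || K_a < 0 || u_bar < 0)
    abort("invalid intestinal geometry or rates", class = "gastrosim_domain_error")
  n_cells <- round(L / dz)
  if (abs(n_cells * dz - L) > 1e-9 * L)
    abort("dz must divide L into a whole number of cells",
          class = "gastrosim_domain_error")
  structure(list(densities = numeric(n_cells + 1),
                 z_nodes = seq(0, L, length.out = n_cells + 1),
                 dz = dz, L = L, u_bar = u_bar, K_a = K_a, l_0 = l_0),
            class = "intestine_field")
}

inj_node <- function(field) {
  n <- length(field$densities)
  # half-away-from-zero rounding, matching the compiled stepper
  min(max(floor(field$l_0 / field$dz + 0.5) + 1L, 3L), n - 1L)
}

#' Total nutrient mass in the intestinal lumen
#'
#' Trapezoidal integral of the linear density over `[0, L]`.
#'
#' @param field An [intestine_field()].
#' @return Mass in grams.
#' @export
intestine_mass <- function(field) {
  s <- field$densities
  n <- length(s)
  field$dz * (sum(s) - 0.5 * (s[1] + s[n]))
}

#' Inject a bolus of emptied nutrient
#'
#' Adds `mass / dz` to the density at the node nearest `l_0`, increasing
#' the trapezoidal mass integral by exactly `mass`.
#'
#' @param field An [intestine_field()].
#' @param mass Nutrient mass entering, g.
#' @return The updated field.
#' @export
inject_bolus <- function(field, mass) {
  if (mass < 0) abort("injected mass must be non-negative",
                      class = "gastrosim_domain_error")
  j <- inj_node(field)
  field$densities[j] <- field$densities[j] + mass / field$dz
  field
}

#' Advance intestinal transport by one explicit step
#'
#' Upwind (backward-difference) advection with first-order absorption:
#' `s_j' = s_j - dt*u_bar*(s_j - s_{j-1})/dz - dt*K_a*s_j`.  The Neumann
#' ends copy their interior neighbours.  Absorbed mass is
#' `dt * K_a * intestine_mass(field)` on the pre-update field; outflow is
#' the advective flux through the last trapezoid panel,
#' `u_bar * dt * (s_{N-1} + s_N)/2`, so the discrete balance
#' `delta(mass) = -absorbed - outflow` holds to round-off.
#'
#' @param field An [intestine_field()].
#' @param dt Time step, s.  Stability requires
#'   `u_bar*dt/dz + K_a*dt <= 1` (positivity-preserving bound).
#' @return A list with `field`, `absorbed` (g) and `outflow` (g).
#' @export
step_transport <- function(field, dt) {
  c_adv <- field$u_bar * dt / field$dz
  if (c_adv + field$K_a * dt > 1) {
    abort(sprintf(
      "unstable transport step: u_bar*dt/dz + K_a*dt = %.3g > 1; dt must be <= %.6g s",
      c_adv + field$K_a * dt, 1 / (field$u_bar / field$dz + field$K_a)),
      class = "gastrosim_stability_error")
  }
  s <- field$densities
  n <- length(s)
  absorbed <- dt * field$K_a * intestine_mass(field)
  outflow <- field$u_bar * dt * 0.5 * (s[n - 1] + s[n])
  s_new <- s
  s_new[2:n] <- s[2:n] - c_adv * (s[2:n] - s[1:(n - 1)]) - field$K_a * dt * s[2:n]
  s_new[1] <- s_new[2]
  field$densities <- s_new
  list(field = field, absorbed = absorbed, outflow = outflow)
}

#' Instantaneous intestinal absorption rate
#'
#' The integral `A = K_a * int_0^L s(z) dz` by the trapezoidal rule; this
#' is the signal sensed by the duodenal brake.
#'
#' @param field An [intestine_field()].
#' @return Absorption rate in g/s.
#' @export
absorption_rate <- function(field) {
  field$K_a * intestine_mass(field)
}

#' Export an intestinal field snapshot
#'
#' Writes a two-column delimited text file (`z_m`, `density_g_per_m`).
#'
#' @param field An [intestine_field()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  readr::write_csv(tibble(z_m = field$z_nodes,
                          density_g_per_m = field$densities), path)
  invisible(path)
}
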