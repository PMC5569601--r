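#' Viscosity of a thickened liquid from its concentration
#'
#' Power-law rheology `mu = a_L * c^b_L`.
#'
#' @param conc Thickener concentration in g/100 ml (vectorised).
#' @param rheology A [rheology_params()].
#' @return Viscosity in Pa s.
#' @examples
#' viscosity_from_concentration(1.5, rheology_params())  # ~ 11 Pa s
#' @export
viscosity_from_concentration <- function(conc, rheology = rheology_params()) {
  if (any(conc < 0)) abort("concentration must be non-negative",
                           class = "gastrosim_domain_error")
  ifelse(conc > 0, rheology$a_L * conc^rheology$b_L, 0)
}

#' Thickener concentration of the gastric content
#'
#' The thickener mass divided by the liquid volume (`liquid_mass / rho_w`),
#' expressed in g/100 ml to match the rheology law.
#'
#' @param thickener_mass Thickener mass in g.
#' @param liquid_mass Liquid mass in g; must be positive.
#' @param rho_w Liquid density in g/ml.
#' @return Concentration in g/100 ml.
#' @examples
#' concentration_from_state(1.5, 100)  # 1.5 g/100 ml
#' @export
concentration_from_state <- function(thickener_mass, liquid_mass, rho_w = 1) {
  if (any(liquid_mass <= 0))
    abort("liquid_mass must be positive to define a concentration",
          class = "gastrosim_degenerate_state")
  if (any(thickener_mass < 0)) abort("thickener_mass must be non-negative",
                                     class = "gastrosim_domain_error")
  100 * thickener_mass * rho_w / liquid_mass
}

#' Gastric secretion rate at a given chyme viscosity
#'
#' `K_sec = lambda_s * mu^b + S_b`: basal secretion plus a power-law
#' response to viscosity.
#'
#' @param mu Chyme viscosity in Pa s (vectorised).
#' @param secretion A [secretion_params()].
#' @return Secretion rate in g/s.
#' @examples
#' secretion_rate(4, secretion_params(0.018, 1.5, 0.018))  # 0.162 g/s
#' @export
secretion_rate <- function(mu, secretion = secretion_params()) {
  if (any(mu < 0)) abort("viscosity must be non-negative",
                         class = "gastrosim_domain_error")
  secretion$lambda_s * mu^secretion$b + secretion$S_b
}

#' Base emptying rate under a hypothesis
#'
#' Evaluates the linear combination of viscosity, gastric volume and
#' secretion rate prescribed by the hypothesis `form` (see
#' [emptying_hypothesis()]).
#'
#' @param hypothesis An [emptying_hypothesis()].
#' @param mu Chyme viscosity, Pa s.
#' @param V_tot Total gastric volume, m^3.
#' @param K_sec Secretion rate, g/s.
#' @return Base emptying rate `gamma_0` in 1/s.
#' @export
gamma0 <- function(hypothesis, mu = 0, V_tot = 0, K_sec = 0) {
  if (any(c(mu, V_tot, K_sec) < 0))
    abort("gamma0 inputs must be non-negative", class = "gastrosim_domain_error")
  h <- hypothesis
  switch(h$form,
         CONSTANT      = h$C1 + 0 * mu,
         VISC_PLUS_VOL = h$m_mu * mu + h$m_s * V_tot,
         VOL_PLUS_C    = h$m_s * V_tot + h$C1,
         VISC_PLUS_C   = h$m_mu * mu + h$C1,
         SEC_PLUS_C    = h$m_sec * K_sec + h$C1,
         SEC_PLUS_VOL  = h$m_sec * K_sec + h$m_s * V_tot)
}

#' Brake-gated effective emptying rate
#'
#' Applies the duodenal-brake switch to the base rate: in `logical` mode
#' emptying stops (`gamma = 0`) whenever the absorption rate `A` exceeds
#' `A_max`; in `smooth` mode the hard switch is replaced with the sigmoid
#' `gamma_0 / (1 + exp(tau_A * (A - A_max)))`, which equals `gamma_0 / 2`
#' exactly at `A = A_max` and converges to the logical switch as
#' `tau_A -> Inf`.  The exponent is clipped at +/-700 so saturation returns
#' the exact limits instead of overflowing.
#'
#' @param A Intestinal absorption rate, g/s (vectorised).
#' @param gamma_0 Base emptying rate, 1/s.
#' @param feedback A [feedback_params()].
#' @return Effective emptying rate in 1/s, in `[0, gamma_0]`.
#' @export
effective_gamma <- function(A, gamma_0, feedback = feedback_params()) {
  if (any(A < 0) || any(gamma_0 < 0))
    abort("A and gamma_0 must be non-negative", class = "gastrosim_domain_error")
  if (!is.finite(feedback$A_max)) return(rep_len(gamma_0, length(A)) + 0 * A)
  if (feedback$mode == "logical") {
    return(ifelse(A > feedback$A_max, 0, gamma_0))
  }
  x <- pmin(pmax(feedback$tau_A * (A - feedback$A_max), -700), 700)
  out <- gamma_0 / (1 + exp(x))
  out[x >= 700] <- 0
  out[x <= -700] <- gamma_0
  out
}
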