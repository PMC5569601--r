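#' Define a liquid meal
#'
#' A meal is described by the initial masses of its three tracked pools:
#' nutrient (e.g. glucose), non-nutrient liquid (assumed to have the density
#' of water), and thickener (a gum such as locust bean gum whose
#' concentration sets the meal viscosity).
#'
#' @param nutrient_mass_0 Initial nutrient mass in grams.
#' @param liquid_mass_0 Initial liquid mass in grams.
#' @param thickener_mass_0 Initial thickener mass in grams.
#' @param label Optional free-text label.
#' @return An object of class `meal_spec`.
#' @examples
#' meal_spec(nutrient_mass_0 = 20.82, liquid_mass_0 = 500)
#' @export
meal_spec <- function(nutrient_mass_0 = 0, liquid_mass_0 = 0,
                      thickener_mass_0 = 0, label = "") {
  if (any(c(nutrient_mass_0, liquid_mass_0, thickener_mass_0) < 0))
    abort("all meal masses must be non-negative", class = "gastrosim_domain_error")
  if (thickener_mass_0 > 0 && liquid_mass_0 <= 0)
    abort("a thickened meal needs liquid_mass_0 > 0 so concentration is defined",
          class = "gastrosim_domain_error")
  structure(list(nutrient_mass_0 = nutrient_mass_0,
                 liquid_mass_0 = liquid_mass_0,
                 thickener_mass_0 = thickener_mass_0,
                 label = label),
            class = "meal_spec")
}

#' Power-law rheology of the thickened liquid
#'
#' Viscosity follows `mu = a_L * c^b_L` where `c` is the thickener
#' concentration in g/100 ml.  The defaults (`a_L = 2`, `b_L = 4.21`)
#' reproduce the anchor points of the locust-bean-gum data behind the model:
#' 1 g/100 ml gives 2 Pa s and 1.5 g/100 ml gives about 11 Pa s.
#'
#' @param a_L Consistency coefficient, Pa s at c = 1 g/100 ml.
#' @param b_L Dimensionless power-law exponent.
#' @param rho_w Liquid density in g/ml (water by default).
#' @return An object of class `rheology_params`.
#' @export
rheology_params <- function(a_L = 2, b_L = 4.21, rho_w = 1) {
  if (a_L <= 0 || b_L <= 0 || rho_w <= 0)
    abort("a_L, b_L and rho_w must all be positive", class = "gastrosim_domain_error")
  structure(list(a_L = a_L, b_L = b_L, rho_w = rho_w),
            class = "rheology_params")
}

#' Viscosity-driven gastric secretion
#'
#' Gastric liquid secretion responds to chyme viscosity as
#' `K_sec = lambda_s * mu^b + S_b`, where `S_b` is the basal rate with no
#' viscous stimulation.  All rates are grams of secreted liquid per second.
#'
#' @param lambda_s Viscosity coefficient (g/s per (Pa s)^b).
#' @param b Dimensionless viscosity exponent.
#' @param S_b Basal secretion rate in g/s.
#' @return An object of class `secretion_params`.
#' @export
secretion_params <- function(lambda_s = 0.018, b = 1.5, S_b = 0.018) {
  if (lambda_s < 0 || S_b < 0)
    abort("lambda_s and S_b must be non-negative", class = "gastrosim_domain_error")
  structure(list(lambda_s = lambda_s, b = b, S_b = S_b),
            class = "secretion_params")
}

hypothesis_forms <- c("CONSTANT", "VISC_PLUS_VOL", "VOL_PLUS_C",
                      "VISC_PLUS_C", "SEC_PLUS_C", "SEC_PLUS_VOL")

# which constants each base-emptying-rate form reads
hypothesis_constants <- list(
  CONSTANT      = "C1",
  VISC_PLUS_VOL = c("m_mu", "m_s"),
  VOL_PLUS_C    = c("m_s", "C1"),
  VISC_PLUS_C   = c("m_mu", "C1"),
  SEC_PLUS_C    = c("m_sec", "C1"),
  SEC_PLUS_VOL  = c("m_sec", "m_s")
)

#' Base emptying-rate hypothesis
#'
#' The base (pre-brake) gastric emptying rate `gamma_0` is a linear
#' combination of chyme viscosity `mu` (Pa s), total gastric volume `V`
#' (m^3) and secretion rate `K_sec` (g/s), in one of five competing forms —
#' plus `CONSTANT`, the fixed-rate special case used by the feedback-only
#' model:
#'
#' * `VISC_PLUS_VOL`: `m_mu * mu + m_s * V`
#' * `VOL_PLUS_C`:    `m_s * V + C1`
#' * `VISC_PLUS_C`:   `m_mu * mu + C1`
#' * `SEC_PLUS_C`:    `m_sec * K_sec + C1`
#' * `SEC_PLUS_VOL`:  `m_sec * K_sec + m_s * V`
#' * `CONSTANT`:      `C1`
#'
#' Only the constants a form reads may be supplied.
#'
#' @param form One of the form names above.
#' @param m_mu Viscosity coefficient, 1/(Pa s^2).
#' @param m_s Volume coefficient, 1/(m^3 s).
#' @param m_sec Secretion coefficient, 1/g.
#' @param C1 Constant emptying rate, 1/s.
#' @return An object of class `emptying_hypothesis`.
#' @examples
#' emptying_hypothesis("SEC_PLUS_C", m_sec = 0.0025, C1 = 6.58e-4)
#' @export
emptying_hypothesis <- function(form, m_mu = NULL, m_s = NULL, m_sec = NULL,
                                C1 = NULL) {
  form <- match.arg(form, hypothesis_forms)
  given <- list(m_mu = m_mu, m_s = m_s, m_sec = m_sec, C1 = C1)
  given <- given[!vapply(given, is.null, logical(1))]
  need <- hypothesis_constants[[form]]
  if (!setequal(names(given), need))
    abort(sprintf("form %s uses exactly {%s}; got {%s}", form,
                  paste(need, collapse = ", "),
                  paste(names(given), collapse = ", ")),
          class = "gastrosim_config_error")
  if (any(unlist(given) < 0))
    abort("hypothesis constants must be non-negative",
          class = "gastrosim_domain_error")
  structure(c(list(form = form), given), class = "emptying_hypothesis")
}

#' Fixed base emptying rate
#'
#' Convenience wrapper for the feedback-only model where `gamma_0` is a
#' single fitted constant.
#'
#' @param gamma0 Base emptying rate, 1/s.
#' @return An `emptying_hypothesis` of form `CONSTANT`.
#' @export
constant_emptying <- function(gamma0) {
  emptying_hypothesis("CONSTANT", C1 = gamma0)
}

#' Duodenal-brake feedback switch
#'
#' When the intestinal absorption rate `A(t)` exceeds the ceiling `A_max`,
#' gastric emptying shuts off.  `mode = "logical"` is the hard on/off
#' switch; `mode = "smooth"` replaces it with a steep sigmoid of sharpness
#' `tau_A` so the emptying rate is a smooth function of `A` (useful inside
#' gradient-based fitting).  `A_max = Inf` disables the brake.
#'
#' @param A_max Absorption-rate ceiling in g/s (may be `Inf`).
#' @param tau_A Sigmoid sharpness in s/g; the default 5e6 makes the smooth
#'   switch practically indistinguishable from the logical one.
#' @param mode `"logical"` or `"smooth"`.
#' @return An object of class `feedback_params`.
#' @export
feedback_params <- function(A_max = Inf, tau_A = 5e6,
                            mode = c("logical", "smooth")) {
  mode <- match.arg(mode)
  if (A_max <= 0) abort("A_max must be positive", class = "gastrosim_domain_error")
  if (tau_A <= 0) abort("tau_A must be positive", class = "gastrosim_domain_error")
  structure(list(A_max = A_max, tau_A = tau_A, mode = mode),
            class = "feedback_params")
}

#' Assemble a simulation configuration
#'
#' Couples a meal, the rheology/secretion laws, an emptying-rate hypothesis
#' and the duodenal-brake switch with the intestinal transport grid.
#' Internally all quantities are SI (seconds, metres, grams, Pa s).
#'
#' @param meal A [meal_spec()].
#' @param hypothesis An [emptying_hypothesis()] (use [constant_emptying()]
#'   for a fixed rate).
#' @param feedback A [feedback_params()].
#' @param rheology A [rheology_params()].
#' @param secretion A [secretion_params()], or `NULL` to disable secretion
#'   (the feedback-only model).
#' @param K_a Intestinal absorption constant, 1/s.
#' @param L Small-intestine length in metres.
#' @param u_bar Mean intestinal flow velocity, m/s.
#' @param l_0 Bolus injection position (metres from the pylorus).
#' @param dz Spatial grid step in metres (default 5 mm).
#' @param dt Time step in seconds, or `NULL` to use 0.9 times the transport
#'   stability bound.  The simulator halves `dt` automatically if the march
#'   goes unstable.
#' @param t_final Simulated horizon in seconds.
#' @param record_every Record state every this many steps (default records
#'   roughly 600 points).
#' @return An object of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(
#'   meal = meal_spec(nutrient_mass_0 = 20.82, liquid_mass_0 = 500),
#'   hypothesis = constant_emptying(9.23e-4),
#'   feedback = feedback_params(A_max = 7e-3),
#'   K_a = 9e-4, t_final = 3600
#' )
#' @export
simulation_config <- function(meal,
                              hypothesis,
                              feedback = feedback_params(),
                              rheology = rheology_params(),
                              secretion = NULL,
                              K_a = 0,
                              L = 2.85,
                              u_bar = 1.7e-4,
                              l_0 = 0.025,
                              dz = L / 570,
                              dt = NULL,
                              t_final = 3600,
                              record_every = NULL) {
  stopifnot(inherits(meal, "meal_spec"),
            inherits(hypothesis, "emptying_hypothesis"),
            inherits(feedback, "feedback_params"),
            inherits(rheology, "rheology_params"))
  if (!is.null(secretion)) stopifnot(inherits(secretion, "secretion_params"))
  if (K_a < 0) abort("K_a must be non-negative", class = "gastrosim_domain_error")
  if (t_final <= 0) abort("t_final must be positive", class = "gastrosim_domain_error")
  if (dz <= 0 || l_0 <= 0 || l_0 >= L)
    abort("need dz > 0 and 0 < l_0 < L", class = "gastrosim_domain_error")
  structure(list(meal = meal, hypothesis = hypothesis, feedback = feedback,
                 rheology = rheology, secretion = secretion, K_a = K_a,
                 L = L, u_bar = u_bar, l_0 = l_0, dz = dz, dt = dt,
                 t_final = t_final, record_every = record_every),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  meal: N0=%g g, liq0=%g g, thickener0=%g g %s\n",
              x$meal$nutrient_mass_0, x$meal$liquid_mass_0,
              x$meal$thickener_mass_0,
              if (nzchar(x$meal$label)) paste0("(", x$meal$label, ")") else ""))
  cat(sprintf("  emptying: %s; brake A_max=%g g/s (%s)\n",
              x$hypothesis$form, x$feedback$A_max, x$feedback$mode))
  cat(sprintf("  secretion: %s; K_a=%g /s; horizon %g min\n",
              if (is.null(x$secretion)) "off" else "on",
              x$K_a, x$t_final / 60))
  invisible(x)
}
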