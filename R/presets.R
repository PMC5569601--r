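preset_file <- function(name) {
  system.file("extdata", "presets", name, package = "gastrosim", mustWork = TRUE)
}

.preset_cache <- new.env(parent = emptyenv())

read_preset_yaml <- function(name) {
  if (is.null(.preset_cache[[name]]))
    .preset_cache[[name]] <- yaml::read_yaml(preset_file(name))
  .preset_cache[[name]]
}

physical_constants <- function() {
  read_preset_yaml("physical.yaml")
}

#' List packaged scenario presets
#'
#' @return A character vector of preset names: `T1a`..`T1h` (feedback-only
#'   glucose drinks), `LVN`, `HVN`, `LVC`, `HVC` (combined
#'   secretion-plus-feedback meals), and `NN_<mu0>` non-nutrient meals such
#'   as `NN_11` (accepted for any positive viscosity).
#' @export
list_presets <- function() {
  c(paste0("T1", letters[1:8]), c("LVN", "HVN", "LVC", "HVC"),
    c("NN_0p06", "NN_2", "NN_5p6", "NN_11"))
}

#' Feedback-only simulation preset
#'
#' Builds the fitted feedback-only configuration for one of the eight
#' glucose-drink conditions `"a"`..`"h"`: a constant base emptying rate, the
#' duodenal brake, and intestinal absorption, with no secretion model.
#' Condition `"a"` was fitted as a pure exponential (brake disabled, no
#' absorption).
#'
#' @param condition One of `"a"`..`"h"`.
#' @param t_final Horizon in seconds (default 240 min).
#' @param mode Brake switch mode, `"logical"` or `"smooth"`.
#' @param liquid_mass_0 Liquid load in g (metadata for the feedback-only
#'   model; it does not influence nutrient emptying).
#' @param ... Further arguments passed to [simulation_config()].
#' @return A [simulation_config()].
#' @export
preset_feedback <- function(condition = letters[1:8], t_final = 14400,
                            mode = "logical", liquid_mass_0 = 500, ...) {
  condition <- match.arg(condition)
  tab <- read_preset_yaml("table1_feedback.yaml")
  row <- tab[[condition]]
  phys <- physical_constants()
  simulation_config(
    meal = meal_spec(nutrient_mass_0 = row$StomN0,
                     liquid_mass_0 = liquid_mass_0,
                     label = row$label),
    hypothesis = constant_emptying(row$gamma0),
    feedback = feedback_params(A_max = row$Amax, tau_A = phys$tauA, mode = mode),
    K_a = row$Ka,
    L = phys$L, u_bar = phys$u, l_0 = phys$l0, dz = phys$dz,
    t_final = t_final, ...)
}

#' Fitted secretion-model parameters
#'
#' Returns the optimal non-nutrient-meal secretion parameters together with
#' the `SEC_PLUS_C` emptying hypothesis they were fitted with, at the
#' Monte-Carlo mean or the mean +/- 2 sd bound.
#'
#' @param which `"mean"`, `"upper"` or `"lower"`.
#' @return A list with elements `secretion` ([secretion_params()]) and
#'   `hypothesis` ([emptying_hypothesis()]).
#' @export
preset_secretion <- function(which = c("mean", "upper", "lower")) {
  which <- match.arg(which)
  row <- read_preset_yaml("table3_secretion.yaml")[[which]]
  list(secretion = secretion_params(lambda_s = row$lambdaS, b = row$b,
                                    S_b = row$Sb),
       hypothesis = emptying_hypothesis("SEC_PLUS_C", m_sec = row$msec,
                                        C1 = row$C1))
}

#' Non-nutrient thickened-meal configuration
#'
#' A meal of thickened liquid with no nutrient: emptying is governed by the
#' secretion-dependent hypothesis alone (the brake has nothing to sense).
#' The thickener load is obtained by inverting the power-law rheology at
#' the requested initial viscosity.
#'
#' @param mu0 Initial chyme viscosity, Pa s (must be at least the viscosity
#'   of water, 1e-3 Pa s).
#' @param liq0 Liquid load, g.
#' @param params Secretion parameters and hypothesis, as returned by
#'   [preset_secretion()].
#' @param t_final Horizon in seconds.
#' @param ... Passed to [simulation_config()].
#' @return A [simulation_config()].
#' @export
nonnutrient_config <- function(mu0, liq0 = 500, params = preset_secretion(),
                               t_final = 3600, ...) {
  if (mu0 < 1e-3)
    abort("mu0 below the viscosity of water (1e-3 Pa s) is not resolvable",
          class = "gastrosim_domain_error")
  phys <- physical_constants()
  rh <- rheology_params(a_L = phys$aL, b_L = phys$bL, rho_w = phys$rho_w)
  conc <- (mu0 / rh$a_L)^(1 / rh$b_L)              # g/100 ml
  simulation_config(
    meal = meal_spec(nutrient_mass_0 = 0, liquid_mass_0 = liq0,
                     thickener_mass_0 = conc * liq0 / 100 / rh$rho_w,
                     label = sprintf("non-nutrient %g Pa s", mu0)),
    hypothesis = params$hypothesis,
    feedback = feedback_params(),                  # brake disabled
    rheology = rh, secretion = params$secretion,
    K_a = 0, L = phys$L, u_bar = phys$u, l_0 = phys$l0, dz = phys$dz,
    t_final = t_final, ...)
}

#' Combined secretion-plus-feedback meal preset
#'
#' The four fitted liquid meals: low/high viscosity nutrient meals
#' (`LVN`, `HVN`) and low/high viscosity low-nutrient controls
#' (`LVC`, `HVC`), each with its own secretion, emptying and absorption
#' parameters.
#'
#' @param meal One of `"LVN"`, `"HVN"`, `"LVC"`, `"HVC"`.
#' @param nutrient_mass_0 Override the preset glucose load, g.
#' @param t_final Horizon in seconds (default 80 min).
#' @param mode Brake switch mode.
#' @param ... Passed to [simulation_config()].
#' @return A [simulation_config()].
#' @export
preset_meal <- function(meal = c("LVN", "HVN", "LVC", "HVC"),
                        nutrient_mass_0 = NULL, t_final = 4800,
                        mode = "logical", ...) {
  meal <- match.arg(meal)
  row <- read_preset_yaml("table4_meals.yaml")[[meal]]
  phys <- physical_constants()
  rh <- rheology_params(a_L = phys$aL, b_L = phys$bL, rho_w = phys$rho_w)
  conc <- (row$mu0 / rh$a_L)^(1 / rh$b_L)
  simulation_config(
    meal = meal_spec(nutrient_mass_0 = nutrient_mass_0 %||% row$StomN0,
                     liquid_mass_0 = row$liq0,
                     thickener_mass_0 = conc * row$liq0 / 100 / rh$rho_w,
                     label = meal),
    hypothesis = emptying_hypothesis("SEC_PLUS_C", m_sec = row$msec,
                                     C1 = row$C1),
    feedback = feedback_params(A_max = row$Amax, tau_A = phys$tauA, mode = mode),
    rheology = rh,
    secretion = secretion_params(lambda_s = row$lambdaS, b = row$b,
                                 S_b = row$Sb),
    K_a = row$Ka,
    L = phys$L, u_bar = phys$u, l_0 = phys$l0, dz = phys$dz,
    t_final = t_final, ...)
}

#' Resolve a scenario preset by name
#'
#' Maps the compact scenario names (see [list_presets()]) to a full
#' [simulation_config()] plus the default observation times and noise
#' scales used by [generate_dataset()].
#'
#' @param name A preset name, e.g. `"T1b"`, `"HVN"`, `"NN_11"`.
#' @param ... Overrides passed to the underlying preset constructor.
#' @return A list with elements `name`, `config`, `times_min`,
#'   `noise_pct` (gastric-content noise, percent of the initial mass).
#' @export
scenario_preset <- function(name, ...) {
  times <- seq(10, 60, 10)
  # replicate scatter of the two conditions it was reported for; a flat
  # 10 percent elsewhere, the magnitude typical of gastric-content data
  noise <- switch(name,
                  T1f = c(16.1, 9.7, 9.7, 11.1, 12.4, 10.6),
                  T1h = c(9.7, 6.0, 9.7, 14.3, 16.6, 16.1),
                  rep(10, 6))
  cfg <-
    if (grepl("^T1[a-h]$", name)) {
      preset_feedback(substr(name, 3, 3), ...)
    } else if (name %in% c("LVN", "HVN", "LVC", "HVC")) {
      preset_meal(name, ...)
    } else if (grepl("^NN_", name)) {
      mu0 <- as.numeric(gsub("p", ".", sub("^NN_", "", name)))
      nonnutrient_config(mu0, ...)
    } else {
      abort(sprintf("unknown preset '%s'; see list_presets()", name),
            class = "gastrosim_config_error")
    }
  list(name = name, config = cfg, times_min = times, noise_pct = noise)
}
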