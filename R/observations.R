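obs_kinds <- c("GASTRIC_MASS", "GASTRIC_FRACTION", "VISCOSITY", "HALF_TIME")

#' Build a validated observation set
#'
#' An observation set is a tibble of time-stamped measurements — gastric
#' content (g or fraction of initial), chyme viscosity (Pa s) or a gastric
#' half-time (s) — from one or more experiments, plus per-experiment
#' metadata (initial viscosity `mu0`, initial liquid load `liq0`, initial
#' nutrient mass `stomN0`) carried in the `meta` attribute.
#'
#' @param data A data frame with columns `experiment`, `time_s`, `value`,
#'   `kind`, and optionally `sd`.
#' @param meta A data frame with column `experiment` and any of `mu0`,
#'   `liq0`, `stomN0`.
#' @return A tibble of class `observation_set`.
#' @export
observation_set <- function(data, meta = NULL) {
  data <- as_tibble(data)
  required <- c("experiment", "time_s", "value", "kind")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    abort(paste("missing observation columns:",
                paste(missing_cols, collapse = ", ")),
          class = "gastrosim_parse_error")
  if (!"sd" %in% names(data)) data$sd <- NA_real_
  bad_kind <- setdiff(unique(data$kind), obs_kinds)
  if (length(bad_kind))
    abort(paste("unknown observation kind:", paste(bad_kind, collapse = ", ")),
          class = "gastrosim_parse_error")
  neg <- which(data$value < 0 | data$time_s < 0)
  if (length(neg))
    abort(sprintf("negative time or value at row %d", neg[1]),
          class = "gastrosim_parse_error")
  dup <- data |>
    dplyr::group_by(.data$experiment, .data$kind) |>
    dplyr::filter(duplicated(.data$time_s) | c(diff(.data$time_s) < 0, FALSE)) |>
    dplyr::ungroup()
  if (nrow(dup))
    abort(sprintf("times must be strictly increasing within a series (experiment %s, t = %g s)",
                  dup$experiment[1], dup$time_s[1]),
          class = "gastrosim_parse_error")
  if (is.null(meta)) meta <- tibble(experiment = unique(data$experiment))
  structure(data[, c("experiment", "time_s", "value", "kind", "sd")],
            class = c("observation_set", class(data)),
            meta = as_tibble(meta))
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("<observation_set> %d observations, %d experiment(s)\n",
              nrow(x), length(unique(x$experiment))))
  NextMethod()
}

obs_meta <- function(obs) attr(obs, "meta")

#' Combine observation sets from several experiments
#'
#' Row-binds the observations and their metadata so multiple conditions can
#' be fitted jointly with shared parameters (the convention of the packaged
#' parameter tables, whose rates are common to all meal sizes of a source).
#'
#' @param ... [observation_set()] objects with distinct experiment names.
#' @return A single [observation_set()].
#' @export
bind_observation_sets <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, logical(1), "observation_set")))
  out <- observation_set(
    dplyr::bind_rows(lapply(sets, as_tibble)),
    meta = dplyr::bind_rows(lapply(sets, obs_meta)))
  solver <- attr(sets[[1]], "solver")
  if (!is.null(solver)) attr(out, "solver") <- solver
  out
}

# evaluate.seed helper: run expr under a fixed RNG state, restoring afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic gastric-emptying dataset
#'
#' Simulates a scenario preset, samples the gastric nutrient mass at the
#' preset's observation times and adds seeded additive Gaussian noise whose
#' per-time standard deviations follow the preset's noise scales
#' (interpreted as percent of the initial mass, the convention of published
#' replicate scatter).  Values are floored at zero.
#'
#' @param preset A preset as returned by [scenario_preset()], or a preset
#'   name.
#' @param seed Integer seed for the noise draw.
#' @param noise If `FALSE`, return the noiseless backbone.
#' @param times_min Override the sampling times (minutes).
#' @return An [observation_set()] with kind `GASTRIC_MASS` and the absolute
#'   noise sd in column `sd`.
#' @export
generate_dataset <- function(preset, seed = 1, noise = TRUE,
                             times_min = NULL) {
  if (is.character(preset)) preset <- scenario_preset(preset)
  cfg <- preset$config
  times <- (times_min %||% preset$times_min) * 60
  cfg$t_final <- max(times) * 1.02
  tr <- simulate(cfg, keep_field = FALSE)
  backbone <- approx(tr$time_s, tr$nutrient_g, xout = times)$y
  n0 <- cfg$meal$nutrient_mass_0
  sd_abs <- rep_len(preset$noise_pct, length(times)) / 100 * n0
  value <- if (noise) {
    with_seed(seed, pmax(0, backbone + rnorm(length(times), 0, sd_abs)))
  } else backbone
  out <- observation_set(
    tibble(experiment = preset$name, time_s = times, value = value,
           kind = "GASTRIC_MASS", sd = sd_abs),
    meta = tibble(experiment = preset$name, mu0 = tr$viscosity_pa_s[1],
                  liq0 = cfg$meal$liquid_mass_0, stomN0 = n0))
  attr(out, "solver") <- list(dt = attr(tr, "dt_used"))
  out
}

#' Generate a synthetic non-nutrient viscosity dataset
#'
#' Emulates the in-vivo design behind the secretion model: several
#' thickened non-nutrient meals of different initial viscosities, each
#' observed as a gastric viscosity time series over an hour plus a measured
#' total-content half-time.  By default only the content-derived half-time
#' carries noise (Gaussian, small coefficient of variation); viscosity
#' noise is optional multiplicative lognormal, off by default because the
#' replicate scatter of in-vivo viscosity maps is large but unquantified.
#'
#' @param initial_viscosities Initial chyme viscosities, Pa s.
#' @param seed Integer seed.
#' @param params Secretion parameters/hypothesis (see [preset_secretion()]).
#' @param liq0 Liquid load per meal, g.
#' @param times_min Viscosity sampling times, minutes.
#' @param visc_sigma Lognormal sigma of the optional viscosity noise
#'   (default 0 = noise on the content-derived half-time only).
#' @param halftime_cv Coefficient of variation of the half-time noise.
#' @return An [observation_set()] with kinds `VISCOSITY` and `HALF_TIME`.
#' @export
nonnutrient_viscosity_set <- function(initial_viscosities = c(0.06, 2, 5.6, 11),
                                      seed = 1,
                                      params = preset_secretion(),
                                      liq0 = 500,
                                      times_min = seq(0, 60, 10),
                                      visc_sigma = 0,
                                      halftime_cv = 0.05) {
  if (any(initial_viscosities < 1e-3))
    abort("initial viscosities below 1e-3 Pa s (water) are not resolvable",
          class = "gastrosim_domain_error")
  with_seed(seed, {
    rows <- list(); metas <- list()
    for (mu0 in initial_viscosities) {
      cfg <- nonnutrient_config(mu0, liq0 = liq0, params = params,
                                t_final = max(times_min) * 60 * 2 + 600)
      tr <- simulate(cfg, keep_field = FALSE)
      mu_sim <- approx(tr$time_s, tr$viscosity_pa_s, xout = times_min * 60)$y
      mu_obs <- mu_sim * exp(rnorm(length(mu_sim), 0, visc_sigma))
      t_half <- half_time(tr, "total")
      if (is.na(t_half))
        abort(sprintf("meal at %g Pa s never reaches half content within horizon", mu0),
              class = "gastrosim_domain_error")
      t_half_obs <- max(0, t_half * (1 + rnorm(1, 0, halftime_cv)))
      ex <- sprintf("NN_%g", mu0)
      rows[[ex]] <- tibble(
        experiment = ex,
        time_s = c(times_min * 60, t_half_obs),
        value = c(mu_obs, t_half_obs),
        kind = c(rep("VISCOSITY", length(mu_obs)), "HALF_TIME"),
        sd = NA_real_)
      metas[[ex]] <- tibble(experiment = ex, mu0 = mu0, liq0 = liq0,
                            stomN0 = 0)
    }
    observation_set(dplyr::bind_rows(rows), meta = dplyr::bind_rows(metas))
  })
}
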