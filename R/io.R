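#' Read an observation table from delimited text
#'
#' Expects a comma-separated file with a header row and columns
#' `time_min` (or `time_s`), `value`, `kind`, and optionally `sd` and
#' `experiment`.  Times in minutes are converted to seconds internally;
#' a `time_s` column is taken as-is.
#'
#' @param path File path.
#' @param mu0,liq0,stomN0 Optional per-experiment metadata (recycled), as
#'   required by the secretion-model objective.
#' @return An [observation_set()].
#' @export
read_observations <- function(path, mu0 = NA_real_, liq0 = NA_real_,
                              stomN0 = NA_real_) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"value" %in% names(df) || !"kind" %in% names(df))
    abort("observation file needs 'value' and 'kind' columns",
          class = "gastrosim_parse_error")
  if ("time_s" %in% names(df)) {
    df$time_s <- df$time_s
  } else if ("time_min" %in% names(df)) {
    df$time_s <- df$time_min * 60
  } else {
    abort("observation file needs a 'time_min' or 'time_s' column",
          class = "gastrosim_parse_error")
  }
  if (!"experiment" %in% names(df)) df$experiment <- "exp1"
  exps <- unique(df$experiment)
  meta <- tibble(experiment = exps,
                 mu0 = rep_len(mu0, length(exps)),
                 liq0 = rep_len(liq0, length(exps)),
                 stomN0 = rep_len(stomN0, length(exps)))
  observation_set(df, meta = meta)
}

#' Write an observation set as delimited text
#'
#' @param obs An [observation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  out <- as_tibble(obs)
  out$time_min <- out$time_s / 60
  readr::write_csv(out[, c("experiment", "time_min", "value", "kind", "sd")],
                   path)
  invisible(path)
}

#' Write a simulated trajectory as delimited text
#'
#' One column per trajectory field, comma-separated, full double precision
#' (round-trips losslessly).  Non-finite values are refused.
#'
#' @param trajectory A `gastro_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  num <- vapply(trajectory, is.numeric, logical(1))
  if (any(vapply(trajectory[num], function(x) any(!is.finite(x)), logical(1))))
    abort("trajectory contains non-finite values; refusing to write",
          class = "gastrosim_io_error")
  readr::write_csv(as_tibble(trajectory), path)
  invisible(path)
}

#' Read back a trajectory table
#'
#' @param path File written by [write_trajectory()].
#' @return A tibble (plain; simulation attributes are not persisted).
#' @export
read_trajectory <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a flat model configuration file
#'
#' A YAML file of unit-suffixed scalar keys, e.g. `StomN0_g`, `liq0_g`,
#' `LBG0_g`, `gamma0_per_s`, `Amax_g_per_s`, `Ka_per_s`, `msec_per_g`,
#' `C1_per_s`, `lambdaS`, `b`, `Sb_g_per_s`, `aL`, `bL`, `tauA_s_per_g`,
#' `L_m`, `u_m_per_s`, `l0_m`, `dz_m`, `dt_s`, `t_final_s`, `mode`,
#' `form`.  Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("StomN0_g", "liq0_g", "LBG0_g", "gamma0_per_s", "Amax_g_per_s",
             "Ka_per_s", "mmu", "ms", "msec_per_g", "C1_per_s", "lambdaS",
             "b", "Sb_g_per_s", "aL", "bL", "tauA_s_per_g", "L_m",
             "u_m_per_s", "l0_m", "dz_m", "dt_s", "t_final_s", "mode",
             "form", "label")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    abort(paste("unknown configuration keys:", paste(bad, collapse = ", ")),
          class = "gastrosim_parse_error")
  g <- function(k, default = NULL) raw[[k]] %||% default
  form <- g("form", if (!is.null(raw$gamma0_per_s)) "CONSTANT" else "SEC_PLUS_C")
  hyp_args <- list(form = form)
  for (pair in list(c("m_mu", "mmu"), c("m_s", "ms"), c("m_sec", "msec_per_g"),
                    c("C1", "C1_per_s"))) {
    if (pair[1] %in% hypothesis_constants[[form]])
      hyp_args[[pair[1]]] <- g(pair[2],
                               if (pair[1] == "C1") g("gamma0_per_s", 0) else 0)
  }
  if (form == "CONSTANT") hyp_args$C1 <- g("gamma0_per_s", g("C1_per_s", 0))
  secretion <- if (!is.null(raw$lambdaS) || !is.null(raw$Sb_g_per_s)) {
    secretion_params(lambda_s = g("lambdaS", 0), b = g("b", 1),
                     S_b = g("Sb_g_per_s", 0))
  } else NULL
  simulation_config(
    meal = meal_spec(nutrient_mass_0 = g("StomN0_g", 0),
                     liquid_mass_0 = g("liq0_g", 500),
                     thickener_mass_0 = g("LBG0_g", 0),
                     label = g("label", "")),
    hypothesis = do.call(emptying_hypothesis, hyp_args),
    feedback = feedback_params(A_max = g("Amax_g_per_s", Inf),
                               tau_A = g("tauA_s_per_g", 5e6),
                               mode = g("mode", "logical")),
    rheology = rheology_params(a_L = g("aL", 2), b_L = g("bL", 4.21)),
    secretion = secretion,
    K_a = g("Ka_per_s", 0), L = g("L_m", 2.85),
    u_bar = g("u_m_per_s", 1.7e-4), l_0 = g("l0_m", 0.025),
    dz = g("dz_m", g("L_m", 2.85) / 570), dt = g("dt_s"),
    t_final = g("t_final_s", 3600))
}

#' Write a run manifest
#'
#' Records the configuration snapshot, package version, seed and the grid
#' actually used, so a run can be reproduced bit-for-bit.
#'
#' @param path Output JSON path.
#' @param config The [simulation_config()] used.
#' @param seed Seed used for any randomness.
#' @param dt_used Time step after any stability refinement.
#' @param outputs Character vector of files the run produced.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, seed = NA_integer_,
                               dt_used = NA_real_, outputs = character()) {
  manifest <- list(
    package = "gastrosim",
    version = as.character(utils::packageVersion("gastrosim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, dt_used_s = dt_used,
    config = rapply(unclass(config), function(x)
      if (is.list(x)) x else unname(x), how = "replace"),
    outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}
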