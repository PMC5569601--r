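#' Akaike information criterion from a least-squares fit
#'
#' `AIC = n * ln(SSE/n) + 2p`, the least-squares form used to rank
#' competing emptying-rate hypotheses.
#'
#' @param sse Sum of squared errors (> 0).
#' @param n Number of data points.
#' @param p Number of fitted parameters.
#' @return The AIC value; `-Inf` with a warning when `sse` is exactly zero.
#' @examples
#' aic(sse = 10, n = 10, p = 1)  # 2
#' @export
aic <- function(sse, n, p) {
  if (n <= 0 || p < 0 || sse < 0)
    abort("need sse >= 0, n > 0, p >= 0", class = "gastrosim_domain_error")
  if (sse == 0) {
    warn("SSE is exactly zero; AIC is -Inf")
    return(-Inf)
  }
  n * log(sse / n) + 2 * p
}

#' Relative likelihood of a model from its AIC
#'
#' `exp((AIC_min - AIC_i)/2)`: how probable model `i` is relative to the
#' AIC-best model.
#'
#' @param aic_i AIC of the candidate model (`>= aic_min`).
#' @param aic_min Smallest AIC among the candidates.
#' @return A value in (0, 1].
#' @examples
#' relative_likelihood(4, 2)  # exp(-1)
#' @export
relative_likelihood <- function(aic_i, aic_min) {
  exp((aic_min - aic_i) / 2)
}

# ---- parameter plumbing ----------------------------------------------------

# map a flat parameter name into / out of a simulation_config
set_config_param <- function(cfg, name, value) {
  switch(name,
    gamma0 = { cfg$hypothesis$C1 <- value },
    Amax = { cfg$feedback$A_max <- value },
    tau_A = { cfg$feedback$tau_A <- value },
    Ka = { cfg$K_a <- value },
    StomN0 = { cfg$meal$nutrient_mass_0 <- value },
    liq0 = { cfg$meal$liquid_mass_0 <- value },
    lambda_s = { cfg$secretion$lambda_s <- value },
    b = { cfg$secretion$b <- value },
    S_b = { cfg$secretion$S_b <- value },
    m_mu = { cfg$hypothesis$m_mu <- value },
    m_s = { cfg$hypothesis$m_s <- value },
    m_sec = { cfg$hypothesis$m_sec <- value },
    C1 = { cfg$hypothesis$C1 <- value },
    a_L = { cfg$rheology$a_L <- value },
    b_L = { cfg$rheology$b_L <- value },
    u_bar = { cfg$u_bar <- value },
    l_0 = { cfg$l_0 <- value },
    abort(sprintf("unknown parameter '%s'; valid names: %s", name,
                  paste(config_param_names(), collapse = ", ")),
          class = "gastrosim_config_error")
  )
  cfg
}

get_config_param <- function(cfg, name) {
  switch(name,
    gamma0 = cfg$hypothesis$C1,
    Amax = cfg$feedback$A_max,
    tau_A = cfg$feedback$tau_A,
    Ka = cfg$K_a,
    StomN0 = cfg$meal$nutrient_mass_0,
    liq0 = cfg$meal$liquid_mass_0,
    lambda_s = cfg$secretion$lambda_s,
    b = cfg$secretion$b,
    S_b = cfg$secretion$S_b,
    m_mu = cfg$hypothesis$m_mu,
    m_s = cfg$hypothesis$m_s,
    m_sec = cfg$hypothesis$m_sec,
    C1 = cfg$hypothesis$C1,
    a_L = cfg$rheology$a_L,
    b_L = cfg$rheology$b_L,
    u_bar = cfg$u_bar,
    l_0 = cfg$l_0,
    abort(sprintf("unknown parameter '%s'; valid names: %s", name,
                  paste(config_param_names(), collapse = ", ")),
          class = "gastrosim_config_error")
  )
}

config_param_names <- function() {
  c("gamma0", "Amax", "tau_A", "Ka", "StomN0", "liq0", "lambda_s", "b",
    "S_b", "m_mu", "m_s", "m_sec", "C1", "a_L", "b_L", "u_bar", "l_0")
}

set_config_params <- function(cfg, par) {
  for (nm in names(par)) cfg <- set_config_param(cfg, nm, par[[nm]])
  cfg
}

# ---- shared bounded multi-start least-squares driver -----------------------

# Levenberg-Marquardt (bounded, with a finite-difference step wide enough to
# sense the brake's switching-time shifts), refined by a Nelder-Mead polish
# that is robust to the residual non-smoothness at switching instants.
fit_nls_driver <- function(resid_fun, start, lower, upper, n_starts = 10,
                           seed = 1, polish = TRUE, polish_maxit = 400) {
  start <- pmin(pmax(start, lower), upper)
  starts <- matrix(start, nrow = 1)
  if (n_starts > 1) {
    lo <- pmax(lower, upper * 1e-4)
    u <- with_seed(seed, lhs::randomLHS(n_starts - 1, length(start)))
    extra <- exp(log(lo)[col(u)] + u * (log(upper) - log(lo))[col(u)])
    extra <- matrix(extra, ncol = length(start))
    starts <- rbind(starts, extra)
  }
  r0 <- resid_fun(start)
  n_resid <- length(r0)
  safe_resid <- function(p) {
    r <- tryCatch(resid_fun(pmin(pmax(p, lower), upper)),
                  error = function(e) NULL)
    if (is.null(r) || length(r) != n_resid || any(!is.finite(r)))
      rep(1e6, n_resid) else r
  }
  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = safe_resid,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 150, epsfcn = 1e-6)),
      error = function(e) NULL)
    if (is.null(res)) next
    sse <- sum(res$fvec^2)
    if (res$info %in% 1:4) any_conv <- TRUE
    if (is.null(best) || sse < best$sse)
      best <- list(par = res$par, sse = sse)
  }
  if (is.null(best)) best <- list(par = start, sse = sum(safe_resid(start)^2))
  if (polish) {
    obj <- function(p) sum(safe_resid(p)^2)
    scale <- pmax(abs(best$par), (upper - lower) * 1e-3, 1e-8)
    nm <- tryCatch(
      if (length(start) == 1) {
        optim(best$par, obj, method = "Brent", lower = lower, upper = upper)
      } else {
        optim(best$par, obj, method = "Nelder-Mead",
              control = list(parscale = scale, maxit = polish_maxit,
                             reltol = 1e-12))
      },
      error = function(e) NULL)
    if (!is.null(nm) && nm$value <= best$sse) {
      best <- list(par = pmin(pmax(nm$par, lower), upper), sse = nm$value)
      any_conv <- TRUE
    }
    # one more LM pass from the polished point
    res <- tryCatch(
      minpack.lm::nls.lm(par = best$par, lower = lower, upper = upper,
                         fn = safe_resid,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 100, epsfcn = 1e-8)),
      error = function(e) NULL)
    if (!is.null(res) && sum(res$fvec^2) <= best$sse)
      best <- list(par = res$par, sse = sum(res$fvec^2))
  }
  names(best$par) <- names(start)
  list(par = best$par, sse = best$sse, converged = any_conv)
}

# Cyclic line scans on a multiplicative grid, shrinking the scan width each
# round.  The brake makes the SSE a fine staircase in Amax and Ka (switch
# patterns flip only at discrete parameter values), so envelope descent by
# grid scanning is what actually locates the optimum there.
coord_refine <- function(obj, par, lower, upper,
                         widths = c(0.5, 0.2, 0.08, 0.03, 0.01),
                         n_grid = 21) {
  cur <- par
  cv <- obj(cur)
  for (w in widths) {
    for (nm in names(par)) {
      grid <- cur[[nm]] * exp(seq(log(1 - w), log(1 + w), length.out = n_grid))
      grid <- grid[grid >= lower[[nm]] & grid <= upper[[nm]]]
      if (!length(grid)) next
      vals <- vapply(grid, function(v) {
        p <- cur; p[[nm]] <- v; obj(p)
      }, numeric(1))
      if (min(vals) < cv) {
        cur[[nm]] <- grid[which.min(vals)]
        cv <- min(vals)
      }
    }
  }
  list(par = cur, sse = cv)
}

new_gastro_fit <- function(par, sse, n, residuals, data, lower, upper,
                           n_starts, seed, converged, flags = character(),
                           model = "feedback", form = NULL) {
  p <- length(par)
  structure(list(par = par, sse = sse, n = n, p = p,
                 aic = if (sse > 0) n * log(sse / n) + 2 * p else -Inf,
                 residuals = residuals, data = data,
                 lower = lower, upper = upper, n_starts = n_starts,
                 seed = seed, converged = converged, flags = flags,
                 model = model, form = form),
            class = "gastro_fit")
}

#' @export
print.gastro_fit <- function(x, ...) {
  cat(sprintf("<gastro_fit> %s model%s: SSE = %.4g, n = %d, p = %d, AIC = %.3f\n",
              x$model, if (is.null(x$form)) "" else paste0(" (", x$form, ")"),
              x$sse, x$n, x$p, x$aic))
  print(tibble(term = names(x$par), estimate = unname(x$par)))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @rdname gastro_fit_methods
#' @title Broom-style accessors for fitted models
#' @param x A `gastro_fit` object.
#' @param ... Unused.
#' @return `tidy()` returns one row per fitted parameter; `glance()` one row
#'   of fit summaries.
#' @export
tidy.gastro_fit <- function(x, ...) {
  tibble(term = names(x$par), estimate = unname(x$par),
         lower = unname(x$lower), upper = unname(x$upper))
}

#' @rdname gastro_fit_methods
#' @export
glance.gastro_fit <- function(x, ...) {
  tibble(sse = x$sse, n = x$n, p = x$p, AIC = x$aic,
         converged = x$converged, n_starts = x$n_starts,
         flags = paste(x$flags, collapse = "; "))
}

# ---- feedback-model fitting ------------------------------------------------

# simulate a config and return gastric nutrient interpolated at given times
predict_nutrient <- function(cfg, times, dt = NULL) {
  dt <- dt %||% (0.9 / (cfg$u_bar / cfg$dz + cfg$K_a))
  res <- sim_fast(cfg, dt, max(times) * 1.02)
  k <- seq_len(res$n_recorded)
  approx(res$time_s[k], res$nutrient_g[k], xout = times, rule = 2)$y
}

#' Fit the duodenal-brake feedback model to emptying data
#'
#' Bounded nonlinear least squares on gastric-content observations: the
#' free parameters (any of `gamma0`, `Amax`, `Ka`, `StomN0`) are adjusted
#' to minimise the unweighted SSE between observed and simulated gastric
#' nutrient mass.  Fitting uses the smooth brake switch (so the objective
#' is continuous in `Amax`) with multi-start Levenberg-Marquardt plus a
#' derivative-free polish; simulation for display can still use the
#' logical switch.
#'
#' @param data An [observation_set()] with kind `GASTRIC_MASS` (grams) or
#'   `GASTRIC_FRACTION` (fraction of the initial mass).
#' @param free Names of the free parameters.
#' @param start Named numeric vector of starting values (defaults are
#'   derived from the data).
#' @param lower,upper Named bounds (defaults span the physiological range).
#' @param config Optional [simulation_config()] template; defaults are
#'   built from the observation metadata.
#' @param n_starts Number of multi-start points (the first is `start`).
#'   With `n_starts = 1` and an explicit `start`, only a local refit is done
#'   (the warm-start mode used by the Monte-Carlo loop).
#' @param seed Seed for the start sampling.
#' @param dt Fixed simulation time step for every objective evaluation;
#'   defaults to 0.9 times the stability bound at the largest admissible
#'   `Ka`.  Synthetic observation sets carry the step they were generated
#'   with (attribute `solver`), which callers can pass here for
#'   self-consistency studies.
#' @param refine_widths Shrinking relative widths of the final coordinate
#'   line-scan refinement (the brake makes the SSE a fine staircase in
#'   `Amax` and `Ka`, where envelope grid descent outperforms gradients).
#' @return A `gastro_fit` object; non-convergence is flagged, not thrown.
#' @export
fit_feedback_model <- function(data,
                               free = c("gamma0", "Amax", "Ka"),
                               start = NULL, lower = NULL, upper = NULL,
                               config = NULL, n_starts = 10, seed = 1,
                               dt = NULL,
                               refine_widths = c(0.5, 0.2, 0.08, 0.03, 0.01)) {
  stopifnot(inherits(data, "observation_set"))
  obs <- data[data$kind %in% c("GASTRIC_MASS", "GASTRIC_FRACTION"), ]
  if (nrow(obs) < length(free))
    abort(sprintf("need at least %d observations to fit %d parameters",
                  length(free), length(free)),
          class = "gastrosim_precondition_error")
  meta <- obs_meta(data)
  exps <- unique(obs$experiment)
  if ("StomN0" %in% free && length(exps) > 1)
    abort("StomN0 can only be freed for a single-experiment dataset",
          class = "gastrosim_config_error")
  n0_of <- vapply(exps, function(ex) {
    m <- if (!is.null(meta) && "stomN0" %in% names(meta))
      meta$stomN0[match(ex, meta$experiment)] else NA_real_
    rows <- obs[obs$experiment == ex, ]
    if (is.finite(m) && m > 0) m
    else if (all(rows$kind == "GASTRIC_FRACTION")) 1 else max(rows$value)
  }, numeric(1))

  if (is.null(config)) {
    config <- simulation_config(
      meal = meal_spec(nutrient_mass_0 = n0_of[[1]], liquid_mass_0 = 500),
      hypothesis = constant_emptying(1e-3),
      feedback = feedback_params(A_max = 1e-2, mode = "smooth"),
      K_a = 1e-3, t_final = max(obs$time_s))
  }
  config$feedback$mode <- "smooth"

  # crude log-linear slope as a gamma0 initialiser (pooled over experiments)
  is_frac_all <- obs$kind == "GASTRIC_FRACTION"
  y <- pmax(obs$value / ifelse(is_frac_all, 1, n0_of[obs$experiment]), 1e-6)
  slope_log <- -coef(lm(log(y) ~ obs$time_s))[[2]]
  user_start <- !is.null(start)
  n0_ref <- max(n0_of)
  default_start <- c(gamma0 = min(max(slope_log, 1e-5), 1e-2), Amax = 1e-2,
                     Ka = 1e-3, StomN0 = n0_ref)
  default_lower <- c(gamma0 = 1e-5, Amax = 1e-4, Ka = 1e-6, StomN0 = n0_ref / 3)
  default_upper <- c(gamma0 = 1e-2, Amax = 5e-2, Ka = 5e-2, StomN0 = n0_ref * 3)
  start <- (start %||% default_start[free])[free]
  lower <- (lower %||% default_lower[free])[free]
  upper <- (upper %||% default_upper[free])[free]
  names(start) <- names(lower) <- names(upper) <- free

  # a dt stable for every admissible Ka keeps the objective continuous
  ka_top <- max(if ("Ka" %in% free) upper[["Ka"]] else 0, config$K_a)
  dt_fit <- dt %||% (0.9 / (config$u_bar / config$dz + ka_top))

  predict_all <- function(p) {
    names(p) <- free
    cfg <- set_config_params(config, as.list(p))
    unlist(lapply(exps, function(ex) {
      rows <- obs[obs$experiment == ex, ]
      cfg_e <- cfg
      if (!"StomN0" %in% free) cfg_e$meal$nutrient_mass_0 <- n0_of[[ex]]
      pred <- predict_nutrient(cfg_e, rows$time_s, dt = dt_fit)
      ifelse(rows$kind == "GASTRIC_FRACTION",
             pred / cfg_e$meal$nutrient_mass_0, pred)
    }), use.names = FALSE)
  }
  obs <- obs[order(match(obs$experiment, exps)), ]  # align with predict_all
  resid_fun <- function(p) obs$value - predict_all(p)
  res <- fit_nls_driver(resid_fun, start, lower, upper,
                        n_starts = n_starts, seed = seed)

  # The objective is piecewise-flat in Amax (above the absorption peak the
  # brake never engages; below it, switching times move in dt-sized jumps),
  # so gradient descent alone cannot place it.  Profile Amax over a
  # deterministic candidate grid with the other parameters refitted each
  # time: under regulation the gastric mass falls at slope ~ -Amax, and the
  # brake-off fit's absorption peak is an upper anchor.
  peak_absorption <- function(p) {
    cfg <- set_config_params(config, as.list(setNames(p, free)))
    max(vapply(exps, function(ex) {
      rows <- obs[obs$experiment == ex, ]
      cfg_e <- cfg
      if (!"StomN0" %in% free) cfg_e$meal$nutrient_mass_0 <- n0_of[[ex]]
      dt_e <- min(dt_fit, 0.9 / (cfg_e$u_bar / cfg_e$dz + cfg_e$K_a))
      res_e <- sim_fast(cfg_e, dt_e, max(rows$time_s) * 1.02)
      max(res_e$absorption_g_s[seq_len(res_e$n_recorded)])
    }, numeric(1)))
  }
  seeds <- list(res$par)
  if ("Amax" %in% free && (n_starts > 1 || !user_start)) {
    others <- setdiff(free, "Amax")
    # steepest per-experiment mass slope: the regulated phase falls at ~Amax
    mass_slope <- max(vapply(exps, function(ex) {
      rows <- obs[obs$experiment == ex, ]
      if (nrow(rows) < 2) return(0)
      abs(coef(lm(rows$value ~ rows$time_s))[[2]]) *
        ifelse(any(rows$kind == "GASTRIC_FRACTION"), n0_of[[ex]], 1)
    }, numeric(1)))
    cand <- mass_slope * c(0.6, 0.85, 1, 1.2)
    peak_a <- peak_absorption(res$par)
    # plus a coarse log ladder so the profile never depends on one heuristic
    ladder <- exp(seq(log(max(lower[["Amax"]], 1e-3)),
                      log(upper[["Amax"]]), length.out = 8))
    cand <- c(cand, peak_a * c(0.8, 0.97), ladder, res$par[["Amax"]])
    cand <- unique(pmin(pmax(cand, lower[["Amax"]]), upper[["Amax"]]))
    profiled <- lapply(cand, function(am) {
      base <- pmin(pmax(start[others], lower[others]), upper[others])
      inner_resid <- function(p) {
        names(p) <- others
        resid_fun(setNames(c(p, am), c(others, "Amax"))[free])
      }
      prof <- fit_nls_driver(inner_resid, base, lower[others], upper[others],
                             n_starts = 1, polish = FALSE)
      inner_obj <- function(p) {
        r <- tryCatch(inner_resid(unlist(p)), error = function(e) NULL)
        if (is.null(r) || any(!is.finite(r))) Inf else sum(r^2)
      }
      prof2 <- coord_refine(inner_obj, prof$par, lower[others], upper[others],
                            widths = c(0.4, 0.15, 0.05))
      if (prof2$sse < prof$sse) prof <- list(par = unlist(prof2$par),
                                             sse = prof2$sse)
      list(par = setNames(c(prof$par, am), c(others, "Amax"))[free],
           sse = prof$sse)
    })
    profiled <- profiled[order(vapply(profiled, `[[`, numeric(1), "sse"))]
    seeds <- c(seeds, lapply(head(profiled, 3), `[[`, "par"))
  }
  if (!is.null(refine_widths)) {
    obj <- function(p) {
      r <- tryCatch(resid_fun(p), error = function(e) NULL)
      if (is.null(r) || any(!is.finite(r))) Inf else sum(r^2)
    }
    for (sd_par in seeds) {
      ref <- coord_refine(obj, sd_par, lower, upper, widths = refine_widths)
      if (ref$sse <= res$sse)
        res <- list(par = ref$par, sse = ref$sse, converged = TRUE)
    }
  }

  flags <- character()
  if ("Amax" %in% free && peak_absorption(res$par) < res$par[["Amax"]])
    flags <- c(flags, "Amax unidentifiable: brake never engages at the optimum")
  if (!res$converged) flags <- c(flags, "optimizer did not converge; best-so-far returned")

  pred <- predict_all(res$par)
  new_gastro_fit(res$par, res$sse, nrow(obs),
                 residuals = tibble(time_s = obs$time_s, observed = obs$value,
                                    fitted = pred,
                                    residual = obs$value - pred),
                 data = data, lower = lower, upper = upper,
                 n_starts = n_starts, seed = seed,
                 converged = res$converged, flags = flags,
                 model = "feedback")
}

# ---- secretion-model fitting ----------------------------------------------

secretion_par_names <- function(form) {
  c("lambda_s", "b", "S_b", hypothesis_constants[[form]])
}

blank_hypothesis <- function(form) {
  consts <- hypothesis_constants[[form]]
  do.call(emptying_hypothesis,
          c(list(form = form), setNames(as.list(rep(0, length(consts))), consts)))
}

secretion_residuals <- function(par, prep, form) {
  sec <- secretion_params(lambda_s = par[["lambda_s"]], b = par[["b"]],
                          S_b = par[["S_b"]])
  hyp <- blank_hypothesis(form)
  for (nm in hypothesis_constants[[form]]) hyp[[nm]] <- par[[nm]]
  out <- numeric(0)
  for (ex in prep) {
    cfg <- ex$cfg
    cfg$secretion <- sec
    cfg$hypothesis <- hyp
    res <- sim_fast(cfg, 0.9 / (cfg$u_bar / cfg$dz + cfg$K_a), ex$horizon)
    k <- seq_len(res$n_recorded)
    if (length(ex$visc_t)) {
      mu_sim <- approx(res$time_s[k], res$viscosity_pa_s[k],
                       xout = ex$visc_t, rule = 2)$y
      out <- c(out, (ex$visc_v - mu_sim) / ex$mu0)
    }
    if (length(ex$halftime)) {
      tot_k <- res$nutrient_g[k] + res$liquid_g[k] + res$thickener_g[k]
      tot <- approx(res$time_s[k], tot_k, xout = ex$halftime, rule = 2)$y
      out <- c(out, sqrt(2) * (0.5 - tot / ex$liq0))
    }
  }
  out
}

# pre-extract everything constant across objective evaluations
secretion_prepare <- function(datasets) {
  maps <- secretion_maps(datasets)
  df <- as.data.frame(datasets)
  lapply(names(maps$mu0), function(ex) {
    rows <- df[df$experiment == ex, ]
    visc <- rows[rows$kind == "VISCOSITY", ]
    ht <- rows[rows$kind == "HALF_TIME", ]
    list(mu0 = maps$mu0[[ex]], liq0 = maps$liq0[[ex]],
         horizon = maps$horizon[[ex]],
         visc_t = visc$time_s, visc_v = visc$value,
         halftime = ht$value,
         cfg = nonnutrient_config(maps$mu0[[ex]], liq0 = maps$liq0[[ex]],
                                  t_final = maps$horizon[[ex]]))
  })
}

secretion_maps <- function(datasets) {
  meta <- obs_meta(datasets)
  if (is.null(meta) || !all(c("mu0", "liq0") %in% names(meta)))
    abort("observation metadata must supply mu0 and liq0 per experiment",
          class = "gastrosim_config_error")
  exps <- unique(datasets$experiment)
  meta <- meta[match(exps, meta$experiment), ]
  if (any(is.na(meta$mu0)) || any(is.na(meta$liq0)))
    abort("observation metadata must supply mu0 and liq0 per experiment",
          class = "gastrosim_config_error")
  horizon <- vapply(exps, function(ex) {
    rows <- datasets[datasets$experiment == ex, ]
    1.1 * max(rows$time_s, rows$value[rows$kind == "HALF_TIME"], 600) + 600
  }, numeric(1))
  list(mu0 = setNames(as.list(meta$mu0), exps),
       liq0 = setNames(as.list(meta$liq0), exps),
       horizon = setNames(as.list(horizon), exps))
}

#' Composite secretion/emptying objective
#'
#' The scalar objective for the secretion model: the sum over experiments
#' of squared viscosity residuals normalised by each experiment's initial
#' viscosity, plus, for each experiment, twice the squared departure of the
#' simulated total gastric content (as a fraction of the liquid load) from
#' one half at the measured half-emptying time.
#'
#' @param par Named parameter vector: `lambda_s`, `b`, `S_b` plus the
#'   constants of `form`.
#' @param datasets An [observation_set()] with `VISCOSITY` and `HALF_TIME`
#'   rows and metadata columns `mu0`, `liq0`.
#' @param form Emptying-rate hypothesis form.
#' @return The non-negative objective value; zero iff the model matches all
#'   normalised viscosities and halves the content exactly at each measured
#'   half-time.
#' @export
composite_secretion_objective <- function(par, datasets,
                                          form = "SEC_PLUS_C") {
  sum(secretion_residuals(par, secretion_prepare(datasets), form)^2)
}

#' Fit the secretion model under one emptying-rate hypothesis
#'
#' Bounded multi-start nonlinear least squares on the composite objective
#' of [composite_secretion_objective()].
#'
#' @inheritParams composite_secretion_objective
#' @param start,lower,upper Named start/bounds for `lambda_s`, `b`, `S_b`
#'   and the form's constants; defaults span the physiological range.
#' @param n_starts,seed Multi-start control.
#' @return A `gastro_fit`.
#' @export
fit_secretion_model <- function(datasets, form = "SEC_PLUS_C",
                                start = NULL, lower = NULL, upper = NULL,
                                n_starts = 10, seed = 1) {
  form <- match.arg(form, setdiff(hypothesis_forms, "CONSTANT"))
  pars <- secretion_par_names(form)
  default_lower <- c(lambda_s = 1e-4, b = 0.1, S_b = 1e-4,
                     m_mu = 1e-6, m_s = 1e-3, m_sec = 1e-5, C1 = 1e-5)
  default_upper <- c(lambda_s = 0.5, b = 3, S_b = 0.1,
                     m_mu = 0.05, m_s = 50, m_sec = 0.05, C1 = 5e-3)
  lower <- (lower %||% default_lower[pars])[pars]
  upper <- (upper %||% default_upper[pars])[pars]
  start <- (start %||% sqrt(lower * upper))[pars]
  names(start) <- names(lower) <- names(upper) <- pars

  prep <- secretion_prepare(datasets)
  resid_fun <- function(p) {
    names(p) <- pars
    secretion_residuals(p, prep, form)
  }
  res <- fit_nls_driver(resid_fun, start, lower, upper,
                        n_starts = n_starts, seed = seed)
  r_opt <- resid_fun(res$par)
  new_gastro_fit(res$par, res$sse, length(r_opt),
                 residuals = tibble(residual = r_opt),
                 data = datasets, lower = lower, upper = upper,
                 n_starts = n_starts, seed = seed,
                 converged = res$converged,
                 model = "secretion", form = form)
}

rank_fits_by_aic <- function(fits) {
  tab <- dplyr::bind_rows(lapply(names(fits), function(f) {
    x <- fits[[f]]
    tibble(form = f, sse = x$sse, n = x$n, p = x$p, AIC = x$aic)
  }))
  tab <- dplyr::arrange(tab, .data$AIC, .data$p)
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  tab$rel_likelihood <- relative_likelihood(tab$AIC, tab$AIC[1])
  tab
}

#' Rank the five emptying-rate hypotheses on one dataset
#'
#' Fits each competing form of the base emptying rate with the composite
#' secretion objective and ranks the fits by AIC (ascending); the relative
#' likelihood of each form versus the best is reported.  Individual fit
#' failures are recorded and the ranking proceeds on the successes.
#'
#' @inheritParams fit_secretion_model
#' @param forms Hypothesis forms to compare (default all five).
#' @return A tibble, one row per form in AIC order, with a `fit` list
#'   column; failures carry `NA` rows, listed last.
#' @export
select_emptying_hypothesis <- function(datasets,
                                       forms = setdiff(hypothesis_forms,
                                                       "CONSTANT"),
                                       n_starts = 10, seed = 1, ...) {
  if (length(forms) < 1)
    abort("need at least one hypothesis form", class = "gastrosim_config_error")
  fits <- list(); fails <- character()
  for (f in forms) {
    fit <- tryCatch(
      fit_secretion_model(datasets, form = f, n_starts = n_starts,
                          seed = seed, ...),
      error = function(e) { fails <<- c(fails, sprintf("%s: %s", f,
                                                       conditionMessage(e)))
                            NULL })
    if (!is.null(fit)) fits[[f]] <- fit
  }
  if (!length(fits))
    abort(paste("every hypothesis fit failed:", paste(fails, collapse = "; ")),
          class = "gastrosim_fit_error")
  tab <- rank_fits_by_aic(fits)
  tab$fit <- fits[tab$form]
  if (length(fails)) attr(tab, "failures") <- fails
  tab
}
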