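test_that("least-squares AIC and relative likelihood follow their closed forms", {
  expect_identical(aic(sse = 10, n = 10, p = 1), 2)
  expect_equal(aic(sse = exp(1) * 10, n = 10, p = 0), 10)
  # one extra parameter at equal SSE costs exactly 2
  expect_equal(aic(5, 20, 4) - aic(5, 20, 3), 2)
  expect_warning(v <- aic(0, 10, 2), "zero")
  expect_identical(v, -Inf)
  expect_identical(relative_likelihood(3, 3), 1)
  expect_equal(relative_likelihood(5, 3), exp(-1))
  # the ~0.9 likelihood ratio corresponds to a ~0.21 AIC gap
  expect_equal(relative_likelihood(3.2107, 3), 0.9, tolerance = 1e-3)
})

test_that("a stored fit satisfies the AIC identity", {
  dat <- nonnutrient_viscosity_set(seed = 5, initial_viscosities = c(2, 11))
  fit <- fit_secretion_model(dat, n_starts = 2, seed = 1)
  expect_equal(fit$aic, fit$n * log(fit$sse / fit$n) + 2 * fit$p)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_identical(nrow(tidy(fit)), 5L)
  expect_identical(glance(fit)$n, fit$n)
})

test_that("the composite objective scores viscosity and half-time departures", {
  dat <- nonnutrient_viscosity_set(seed = 2, visc_sigma = 0, halftime_cv = 0)
  truth <- c(lambda_s = 0.018, b = 1.5, S_b = 0.018, m_sec = 0.0025,
             C1 = 6.58e-4)
  # simulated data scored against itself is at the discretisation floor
  expect_lt(composite_secretion_objective(truth, dat), 1e-3)
  # doubling all viscosity residuals quadruples the viscosity term
  # (single-meal set so the residual layout is [viscosity..., half-time])
  one <- nonnutrient_viscosity_set(seed = 2, initial_viscosities = 11,
                                   visc_sigma = 0.2, halftime_cv = 0)
  prep <- gastrosim:::secretion_prepare(one)
  r <- gastrosim:::secretion_residuals(truth, prep, "SEC_PLUS_C")
  n_visc <- length(prep[[1]]$visc_t)
  sim_mu <- prep[[1]]$visc_v - r[seq_len(n_visc)] * prep[[1]]$mu0
  prep2 <- prep
  prep2[[1]]$visc_v <- sim_mu + 2 * (prep[[1]]$visc_v - sim_mu)
  r2 <- gastrosim:::secretion_residuals(truth, prep2, "SEC_PLUS_C")
  expect_equal(sum(r2[seq_len(n_visc)]^2), 4 * sum(r[seq_len(n_visc)]^2),
               tolerance = 1e-10)
})

test_that("a half-content mismatch contributes 2*(0.5 - fraction)^2", {
  # one meal, perfect viscosity match, content 0.6*liq0 at the recorded
  # half-time: objective = 2*(0.1)^2
  dat <- nonnutrient_viscosity_set(seed = 3, initial_viscosities = 2,
                                   visc_sigma = 0, halftime_cv = 0)
  truth <- c(lambda_s = 0.018, b = 1.5, S_b = 0.018, m_sec = 0.0025,
             C1 = 6.58e-4)
  prep <- gastrosim:::secretion_prepare(dat)
  # doctor the prepared half-time so the simulated fraction there is 0.6
  cfg <- prep[[1]]$cfg
  cfg$secretion <- secretion_params(0.018, 1.5, 0.018)
  cfg$hypothesis <- emptying_hypothesis("SEC_PLUS_C", m_sec = 0.0025,
                                        C1 = 6.58e-4)
  tr <- simulate(cfg, keep_field = FALSE)
  tot_frac <- (tr$total_g) / prep[[1]]$liq0
  t_at_06 <- approx(tot_frac, tr$time_s, xout = 0.6)$y
  prep[[1]]$halftime <- t_at_06
  prep[[1]]$visc_t <- numeric(0)  # drop viscosity rows
  prep[[1]]$visc_v <- numeric(0)
  r <- gastrosim:::secretion_residuals(truth, prep, "SEC_PLUS_C")
  expect_equal(sum(r^2), 2 * 0.1^2, tolerance = 1e-3)
})

test_that("missing metadata is a configuration error", {
  df <- tibble::tibble(experiment = "x", time_s = c(0, 600), value = c(2, 1.5),
                       kind = "VISCOSITY", sd = NA_real_)
  obs <- observation_set(df)
  expect_error(composite_secretion_objective(c(lambda_s = 0.01, b = 1,
                                               S_b = 0.01, m_sec = 1e-3,
                                               C1 = 1e-4), obs),
               class = "gastrosim_config_error")
})

test_that("feedback fitting enforces its preconditions and flags flatness", {
  obs1 <- observation_set(
    tibble::tibble(experiment = "e", time_s = c(600, 1200, 1800, 2400),
                   value = c(18, 11, 6.5, 4), kind = "GASTRIC_MASS",
                   sd = NA_real_),
    meta = tibble::tibble(experiment = "e", stomN0 = 30))
  expect_error(fit_feedback_model(obs1[1, ], free = c("gamma0", "Amax", "Ka",
                                                      "StomN0")),
               class = "gastrosim_precondition_error")
  # data on an exact exponential: gamma0 is recovered, Amax flagged flat
  g0 <- 8e-4
  tt <- seq(600, 3600, 600)
  obs2 <- observation_set(
    tibble::tibble(experiment = "e", time_s = tt, value = 20 * exp(-g0 * tt),
                   kind = "GASTRIC_MASS", sd = NA_real_),
    meta = tibble::tibble(experiment = "e", stomN0 = 20))
  fit <- fit_feedback_model(obs2, free = c("gamma0", "Amax"),
                            start = c(gamma0 = 1.6e-3, Amax = 3e-2),
                            n_starts = 2, seed = 1)
  expect_equal(unname(fit$par[["gamma0"]]), g0, tolerance = 0.02)
  expect_true(any(grepl("Amax unidentifiable", fit$flags)))
})

test_that("noise-free self-generated data are recovered from a perturbed start", {
  # smooth-brake self-consistency: both conditions of the shared parameter
  # row fitted jointly, sigmoid sharpness resolved by the solver step
  truth <- c(gamma0 = 9.22e-4, Amax = 1e-2, Ka = 1.7e-3)
  mkp <- function(nm) {
    p <- scenario_preset(nm, mode = "smooth")
    p$config$feedback$tau_A <- 2e3
    p
  }
  obs <- bind_observation_sets(generate_dataset(mkp("T1e"), noise = FALSE),
                               generate_dataset(mkp("T1f"), noise = FALSE))
  fit <- fit_feedback_model(obs, start = 2 * truth, n_starts = 4,
                            dt = attr(obs, "solver")$dt,
                            config = mkp("T1e")$config)
  expect_true(all(abs(fit$par[names(truth)] - truth) / truth < 0.01))
})

test_that("fitting is invariant to a time-unit round trip", {
  # minutes-labelled file and seconds-labelled file describe the same data
  tmp_min <- withr::local_tempfile(fileext = ".csv")
  tmp_s <- withr::local_tempfile(fileext = ".csv")
  tt_min <- seq(10, 60, 10)
  vals <- 20 * exp(-1e-3 * tt_min * 60)
  readr::write_csv(tibble::tibble(time_min = tt_min, value = vals,
                                  kind = "GASTRIC_MASS"), tmp_min)
  readr::write_csv(tibble::tibble(time_s = tt_min * 60, value = vals,
                                  kind = "GASTRIC_MASS"), tmp_s)
  f1 <- fit_feedback_model(read_observations(tmp_min, stomN0 = 20),
                           free = "gamma0", n_starts = 2, seed = 1)
  f2 <- fit_feedback_model(read_observations(tmp_s, stomN0 = 20),
                           free = "gamma0", n_starts = 2, seed = 1)
  expect_equal(f1$par, f2$par, tolerance = 1e-8)
  expect_equal(unname(f1$par[["gamma0"]]), 1e-3, tolerance = 0.01)
})

test_that("hypothesis ranking is by AIC with ties broken by parsimony", {
  mk <- function(sse, n, p, form) {
    gastrosim:::new_gastro_fit(par = setNames(rep(1, p), paste0("c", 1:p)),
                               sse = sse, n = n,
                               residuals = tibble::tibble(residual = 0),
                               data = NULL, lower = rep(0, p),
                               upper = rep(2, p), n_starts = 1, seed = 1,
                               converged = TRUE, model = "secretion",
                               form = form)
  }
  fits <- list(A = mk(1, 10, 3, "A"), B = mk(1, 10, 2, "B"),
               C = mk(2, 10, 2, "C"))
  tab <- gastrosim:::rank_fits_by_aic(fits)
  expect_identical(tab$form, c("B", "A", "C"))
  expect_identical(tab$rel_likelihood[1], 1)
  expect_equal(tab$rel_likelihood[2], exp(-1))
})

test_that("model selection recovers the generating form on clean data", {
  dat <- nonnutrient_viscosity_set(seed = 41, visc_sigma = 0,
                                   halftime_cv = 0)
  tab <- select_emptying_hypothesis(dat, n_starts = 3, seed = 7)
  expect_identical(tab$form[1], "SEC_PLUS_C")
  expect_true(all(diff(tab$AIC) >= 0))
  expect_true(all(tab$rel_likelihood <= 1 & tab$rel_likelihood > 0))
  # single-form selection is trivially that form
  tab1 <- select_emptying_hypothesis(dat, forms = "VISC_PLUS_C",
                                     n_starts = 2, seed = 7)
  expect_identical(tab1$form, "VISC_PLUS_C")
})
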