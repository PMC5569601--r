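#' Noise-injection Monte-Carlo assessment of parameter estimates
#'
#' Repeatedly perturbs the observations with seeded random noise, refits
#' the feedback model, and collects the optima.  The unperturbed data are
#' fitted first (full multi-start); each iteration then refits from that
#' optimum (warm start) unless `cold_start = TRUE`.  Noise is drawn per
#' observation from its `sd` column (or `noise_sd`): uniformly on
#' `[-sd, +sd]` by default — the literal reading of noise "taken from the
#' range of maximum deviation" — or Gaussian with that sd.
#'
#' @param data An [observation_set()] with gastric-content rows and noise
#'   scales in the `sd` column.
#' @param free,lower,upper,config Passed to [fit_feedback_model()].
#' @param noise `"uniform"` or `"gaussian"`.
#' @param noise_sd Optional per-observation scale overriding `data$sd`.
#' @param n_iter Number of iterations (published workflows use 5000; tests
#'   use far fewer).
#' @param seed Integer seed; results are reproducible given `seed`.
#' @param cold_start Refit each iteration from scratch instead of from the
#'   unperturbed optimum.
#' @param dt Fixed simulation step forwarded to [fit_feedback_model()].
#' @param refine_widths Line-scan widths for the per-iteration warm refits;
#'   `NULL` (default) refits by Levenberg-Marquardt alone from the warm
#'   start, the published workflow's protocol (flat directions then stay
#'   put, which is what the histograms are meant to reveal).
#' @param n_starts Multi-start count for the initial (and any cold) fits.
#' @return An object of class `gastro_mc`: list with `samples` (tibble:
#'   `iteration`, `term`, `estimate`), `base_fit`, `n_iter`, `n_failed`,
#'   `seed`, `noise`.
#' @export
run_monte_carlo <- function(data, free = c("gamma0", "Amax", "Ka"),
                            noise = c("uniform", "gaussian"),
                            noise_sd = NULL, n_iter = 100, seed = 1,
                            lower = NULL, upper = NULL, config = NULL,
                            cold_start = FALSE, n_starts = 10, dt = NULL,
                            refine_widths = NULL) {
  noise <- match.arg(noise)
  if (n_iter < 1) abort("n_iter must be at least 1",
                        class = "gastrosim_domain_error")
  gastric <- data$kind %in% c("GASTRIC_MASS", "GASTRIC_FRACTION")
  sds <- noise_sd %||% data$sd
  if (any(is.na(sds[gastric])))
    abort("every gastric observation needs a noise scale (sd column or noise_sd)",
          class = "gastrosim_config_error")

  base_fit <- fit_feedback_model(data, free = free, lower = lower,
                                 upper = upper, config = config,
                                 n_starts = n_starts, seed = seed, dt = dt)
  draws <- with_seed(seed, {
    lapply(seq_len(n_iter), function(i) {
      eps <- switch(noise,
                    uniform = runif(sum(gastric), -1, 1) * sds[gastric],
                    gaussian = rnorm(sum(gastric), 0, sds[gastric]))
      eps
    })
  })

  samples <- vector("list", n_iter)
  n_failed <- 0L
  for (i in seq_len(n_iter)) {
    pert <- data
    pert$value[gastric] <- pmax(0, data$value[gastric] + draws[[i]])
    fit_i <- tryCatch(
      fit_feedback_model(pert, free = free,
                         start = if (cold_start) NULL else base_fit$par,
                         lower = lower, upper = upper, config = config,
                         n_starts = if (cold_start) n_starts else 1,
                         seed = seed + i, dt = dt,
                         refine_widths = refine_widths),
      error = function(e) NULL)
    if (is.null(fit_i)) { n_failed <- n_failed + 1L; next }
    samples[[i]] <- tibble(iteration = i, term = names(fit_i$par),
                           estimate = unname(fit_i$par))
  }
  structure(list(samples = dplyr::bind_rows(samples), base_fit = base_fit,
                 n_iter = n_iter, n_failed = n_failed, seed = seed,
                 noise = noise),
            class = "gastro_mc")
}

#' @export
print.gastro_mc <- function(x, ...) {
  cat(sprintf("<gastro_mc> %d iterations (%d failed), %s noise, seed %d\n",
              x$n_iter, x$n_failed, x$noise, x$seed))
  print(glance(x))
  invisible(x)
}

#' @rdname gastro_mc_methods
#' @title Broom-style accessors for Monte-Carlo results
#' @param x A `gastro_mc` object.
#' @param ... Unused.
#' @return `tidy()` returns per-parameter means and standard deviations;
#'   `glance()` a one-row run summary.
#' @export
tidy.gastro_mc <- function(x, ...) {
  x$samples |>
    dplyr::group_by(term = .data$term) |>
    dplyr::summarise(mean = mean(.data$estimate), sd = sd(.data$estimate),
                     cv = sd(.data$estimate) / mean(.data$estimate),
                     n = dplyr::n(), .groups = "drop")
}

#' @rdname gastro_mc_methods
#' @export
glance.gastro_mc <- function(x, ...) {
  tibble(n_iter = x$n_iter, n_failed = x$n_failed, noise = x$noise,
         seed = x$seed)
}

#' Binned histogram counts of Monte-Carlo samples
#'
#' The tabular form of the parameter histograms: per-parameter equal-width
#' bins with counts, suitable for delimited-text export.
#'
#' @param mc A `gastro_mc` object.
#' @param bins Number of bins per parameter.
#' @return A tibble with `term`, `bin_mid`, `bin_lo`, `bin_hi`, `count`.
#' @export
mc_histogram <- function(mc, bins = 30) {
  stopifnot(inherits(mc, "gastro_mc"))
  mc$samples |>
    dplyr::group_by(term = .data$term) |>
    dplyr::reframe({
      h <- graphics::hist(.data$estimate, breaks = bins, plot = FALSE)
      tibble(bin_mid = h$mids, bin_lo = head(h$breaks, -1),
             bin_hi = tail(h$breaks, -1), count = h$counts)
    })
}

#' Parameter bounds from Monte-Carlo samples
#'
#' Mean +/- 2 standard deviations per parameter, covering about 95 percent
#' of the Monte-Carlo estimates; these bounds are the standard box for
#' downstream constrained fitting.  Optionally floors the lower bound at
#' zero for physical rates (off by default).
#'
#' @param mc A `gastro_mc` object, or a tibble with `term` and `estimate`
#'   columns.
#' @param floor_at_zero Floor lower bounds at 0.
#' @return A tibble with `term`, `mean`, `sd`, `lower`, `upper`.
#' @export
bounds_from_samples <- function(mc, floor_at_zero = FALSE) {
  samples <- if (inherits(mc, "gastro_mc")) mc$samples else as_tibble(mc)
  counts <- table(samples$term)
  if (any(counts < 2))
    abort("need at least 2 samples per parameter",
          class = "gastrosim_precondition_error")
  out <- samples |>
    dplyr::group_by(term = .data$term) |>
    dplyr::summarise(mean = mean(.data$estimate), sd = sd(.data$estimate),
                     .groups = "drop") |>
    dplyr::mutate(lower = .data$mean - 2 * .data$sd,
                  upper = .data$mean + 2 * .data$sd)
  if (floor_at_zero) out$lower <- pmax(out$lower, 0)
  out
}
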