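# Parametric models for focal-area staying time. Four candidate families
# (exponential, gamma, lognormal, Weibull), optionally with a camera-level
# random effect on the log mean, fitted by MCMC with weakly informative
# priors and compared by WAIC. The selected family's expected staying time
# feeds the REST density equation.

STAY_FAMILIES <- c("exponential", "gamma", "lognormal", "weibull")

# Each family is parameterised on an unconstrained scale so the sampler can
# random-walk freely. `mean` is the analytic mean of the fitted family.
stay_family <- function(family) {
  fam <- stay_family_impl(family)
  raw_mean <- fam$mean
  fam$mean <- function(th) unname(raw_mean(th))
  fam
}

stay_family_impl <- function(family) {
  switch(family,
    exponential = list(
      npar = 1L, par_names = "log_rate",
      loglik = function(th, t, off) dexp(t, exp(th[1L] - off), log = TRUE),
      mean = function(th) exp(-th[1L]),
      init = function(t) c(log_rate = -log(mean(t)))),
    gamma = list(
      npar = 2L, par_names = c("log_shape", "log_rate"),
      loglik = function(th, t, off) {
        dgamma(t, shape = exp(th[1L]), rate = exp(th[2L] - off), log = TRUE)
      },
      mean = function(th) exp(th[1L] - th[2L]),
      init = function(t) {
        m <- mean(t); v <- var(t) + 1e-9
        c(log_shape = log(m^2 / v), log_rate = log(m / v))
      }),
    lognormal = list(
      npar = 2L, par_names = c("meanlog", "log_sdlog"),
      loglik = function(th, t, off) {
        dlnorm(t, meanlog = th[1L] + off, sdlog = exp(th[2L]), log = TRUE)
      },
      mean = function(th) exp(th[1L] + exp(2 * th[2L]) / 2),
      init = function(t) c(meanlog = mean(log(t)),
                           log_sdlog = log(sd(log(t)) + 1e-6)),
      meanlog_offset = TRUE),
    weibull = list(
      npar = 2L, par_names = c("log_shape", "log_scale"),
      loglik = function(th, t, off) {
        dweibull(t, shape = exp(th[1L]), scale = exp(th[2L] + off), log = TRUE)
      },
      mean = function(th) exp(th[2L]) * gamma(1 + exp(-th[1L])),
      init = function(t) c(log_shape = 0, log_scale = log(mean(t)))),
    stop_boarest(sprintf("Unknown staying-time family '%s'; use one of {%s}.",
                         family, paste(STAY_FAMILIES, collapse = ", ")))
  )
}

#' Fit one staying-time distribution family
#'
#' Bayesian fit of a parametric distribution to measured staying times,
#' with normal(0, `staying_sd`) priors on the unconstrained (log-scale)
#' parameters. With `random_effect = TRUE` each camera receives a normal
#' multiplicative offset on the mean (additive on the log scale) with an
#' estimated between-camera s.d. WAIC is computed from the pointwise
#' posterior log likelihoods as -2(lppd - p_WAIC), with p_WAIC the summed
#' pointwise posterior variances of the log likelihood.
#'
#' @param times_s Staying times in seconds, all > 0.
#' @param family One of `"exponential"`, `"gamma"`, `"lognormal"`,
#'   `"weibull"`.
#' @param camera_ids Camera id per observation; required when
#'   `random_effect` is `TRUE`.
#' @param random_effect Include a camera-level random effect?
#' @param config A [boarest_config()] (supplies the prior s.d.).
#' @param iterations,burn_in,thin,seed MCMC settings for this fit.
#' @return A `boarest_staying` object: posterior draws, WAIC,
#'   `expected_staying_time_s` (posterior mean of the analytic mean) and
#'   the posterior draws of the mean for uncertainty propagation.
#' @export
fit_staying_time <- function(times_s, family, camera_ids = NULL,
                             random_effect = FALSE,
                             config = boarest_config(),
                             iterations = 4000, burn_in = 1000, thin = 5,
                             seed = 1) {
  if (any(!is.finite(times_s)) || any(times_s <= 0)) {
    stop_boarest("All staying times must be positive and finite.")
  }
  fam <- stay_family(family)
  if (random_effect && is.null(camera_ids)) {
    stop_boarest("camera_ids are required for a camera random effect.")
  }
  prior_sd <- config$priors$staying_sd
  n <- length(times_s)

  if (random_effect) {
    cam <- factor(camera_ids)
    J <- nlevels(cam)
    cam_idx <- as.integer(cam)
    init <- c(fam$init(times_s), rep(0, J), log_tau = log(0.3))
    names(init) <- c(fam$par_names, paste0("b_", levels(cam)), "log_tau")
    lp <- function(th) {
      b <- th[fam$npar + seq_len(J)]
      tau <- exp(th[fam$npar + J + 1L])
      off <- b[cam_idx]
      sum(fam$loglik(th[seq_len(fam$npar)], times_s, off)) +
        sum(dnorm(b, 0, tau, log = TRUE)) +
        dnorm(log(tau), log(0.3), 1, log = TRUE) +
        sum(dnorm(th[seq_len(fam$npar)], 0, prior_sd, log = TRUE))
    }
    track <- function(th) {
      fam$loglik(th[seq_len(fam$npar)], times_s, th[fam$npar + cam_idx])
    }
    npar_eff <- fam$npar + J + 1L
  } else {
    init <- fam$init(times_s)
    lp <- function(th) {
      sum(fam$loglik(th, times_s, 0)) +
        sum(dnorm(th, 0, prior_sd, log = TRUE))
    }
    track <- function(th) fam$loglik(th, times_s, 0)
    npar_eff <- fam$npar
  }

  set.seed(seed)
  chain <- amwg_chain(lp, init, iterations, burn_in, thin, track = track)
  ll <- chain$tracked                       # S x n pointwise log-likelihood
  S <- nrow(ll)
  lppd <- sum(apply(ll, 2L, function(v) {
    mx <- max(v); mx + log(mean(exp(v - mx)))
  }))
  p_waic <- sum(apply(ll, 2L, var))
  waic <- -2 * (lppd - p_waic)

  mean_draws <- apply(chain$draws[, seq_len(fam$npar), drop = FALSE], 1L,
                      fam$mean)
  structure(list(family = family, random_effect = random_effect,
                 draws = chain$draws, n = n, npar = npar_eff,
                 waic = waic, lppd = lppd, p_waic = p_waic,
                 mean_draws = mean_draws,
                 expected_staying_time_s = mean(mean_draws),
                 params = colMeans(chain$draws[, seq_len(fam$npar),
                                               drop = FALSE]),
                 data_fingerprint = c(n, sum(times_s), sum(log(times_s)))),
            class = "boarest_staying")
}

#' Analytic expected staying time of a fitted model
#'
#' Closed-form mean of the fitted family evaluated at the posterior mean
#' parameters (exponential: 1/rate; gamma: shape/rate; lognormal:
#' exp(mu + sigma^2/2); Weibull: scale * Gamma(1 + 1/shape)).
#'
#' @param model A `boarest_staying` fit.
#' @return Expected staying time in seconds.
#' @export
expected_staying_time <- function(model) {
  stopifnot(inherits(model, "boarest_staying"))
  fam <- stay_family(model$family)
  m <- fam$mean(model$params)
  if (!is.finite(m) || m <= 0) {
    stop_boarest("Fitted parameters give an undefined or non-positive mean.")
  }
  m
}

#' Select the best staying-time model by WAIC
#'
#' @param models List of `boarest_staying` fits of the *same* data.
#' @return The minimum-WAIC model; exact ties break toward fewer
#'   parameters, then input order.
#' @export
select_best <- function(models) {
  stopifnot(length(models) >= 2L,
            all(vapply(models, inherits, logical(1L), "boarest_staying")))
  fps <- vapply(models, function(m) m$data_fingerprint, numeric(3L))
  if (any(abs(fps - fps[, 1L]) > 1e-8 * (1 + abs(fps[, 1L])))) {
    stop_boarest("All candidate models must be fitted to the same data.")
  }
  waics <- vapply(models, function(m) m$waic, numeric(1L))
  npars <- vapply(models, function(m) m$npar, numeric(1L))
  best <- order(waics, npars)[1L]
  models[[best]]
}

#' Fit and compare all candidate staying-time models
#'
#' Runs the full candidate sweep (four families, with and without the
#' camera random effect when `camera_ids` are given) and selects the
#' minimum-WAIC model.
#'
#' @inheritParams fit_staying_time
#' @param random_effect_sweep Also fit each family with the camera random
#'   effect (doubles the candidate set).
#' @return List with `models` (all fits), `comparison` (tibble of WAICs)
#'   and `best`.
#' @export
staying_time_sweep <- function(times_s, camera_ids = NULL,
                               random_effect_sweep = !is.null(camera_ids),
                               config = boarest_config(),
                               iterations = 4000, burn_in = 1000, thin = 5,
                               seed = 1) {
  grid <- tidyr::expand_grid(
    family = STAY_FAMILIES,
    random_effect = if (random_effect_sweep) c(FALSE, TRUE) else FALSE)
  models <- purrr::pmap(grid, function(family, random_effect) {
    fit_staying_time(times_s, family, camera_ids = camera_ids,
                     random_effect = random_effect, config = config,
                     iterations = iterations, burn_in = burn_in,
                     thin = thin, seed = seed)
  })
  comparison <- purrr::map_dfr(models, function(m) {
    tibble::tibble(family = m$family, random_effect = m$random_effect,
                   waic = m$waic, p_waic = m$p_waic,
                   expected_staying_time_s = m$expected_staying_time_s)
  }) |> dplyr::arrange(.data$waic)
  list(models = models, comparison = comparison, best = select_best(models))
}

#' @export
print.boarest_staying <- function(x, ...) {
  cat(sprintf("<staying-time fit> %s%s, n = %d\n", x$family,
              if (x$random_effect) " + camera random effect" else "", x$n))
  cat(sprintf("  WAIC = %.1f (p_WAIC = %.1f); E[staying time] = %.2f s\n",
              x$waic, x$p_waic, x$expected_staying_time_s))
  invisible(x)
}

#' @export
tidy.boarest_staying <- function(x, ...) {
  draws <- x$draws
  tibble::tibble(
    term = colnames(draws),
    estimate = colMeans(draws),
    std.error = apply(draws, 2L, sd),
    conf.low = apply(draws, 2L, quantile, 0.025),
    conf.high = apply(draws, 2L, quantile, 0.975))
}

#' @export
glance.boarest_staying <- function(x, ...) {
  tibble::tibble(family = x$family, random_effect = x$random_effect,
                 nobs = x$n, waic = x$waic, p_waic = x$p_waic,
                 expected_staying_time_s = x$expected_staying_time_s)
}
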