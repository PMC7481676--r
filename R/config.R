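#' Study configuration
#'
#' Bundles the geometric, temporal and MCMC settings shared by every stage of
#' the joint model. Defaults reproduce the field protocol the model was
#' developed for: a 1.9 m equilateral-triangle focal area, a 500 m landscape
#' buffer summarised into 4 principal-component axes, monthly parameters, and
#' 50 000 MCMC iterations with 10 000 burn-in, thinning 20 and 3 chains.
#'
#' @param focal_side_m Side length (m) of the equilateral-triangle focal area.
#' @param buffer_radius_m Radius (m) of the landscape buffer around each
#'   camera. Metadata only: compositions are supplied pre-extracted.
#' @param n_pc_axes Number of principal-component axes used as density
#'   covariates.
#' @param months Ordered character vector of month labels.
#' @param age_classes Character vector of age classes modelled separately.
#' @param mcmc Named list: `iterations`, `burn_in`, `thin`, `chains`, `seed`.
#' @param priors Named list: `alpha_low`/`alpha_high` (uniform support of the
#'   habitat coefficients), `catchability_low`/`catchability_high` (uniform
#'   support of trap catchability), `dispersion_scale` (half-Cauchy scale on
#'   1/sqrt(k) for the negative-binomial dispersion), `staying_sd` (normal
#'   s.d. on staying-time parameters, log scale).
#' @param min_activity_n Minimum detections needed before a monthly activity
#'   level is estimated on its own (smaller samples pool adjacent months).
#' @param min_staying_n Minimum staying-time sample per month/age class.
#'
#' @return An object of class `boarest_config` (a validated named list).
#' @export
#' @examples
#' cfg <- boarest_config(mcmc = list(iterations = 2000, burn_in = 500))
#' cfg$mcmc$thin
boarest_config <- function(focal_side_m = 1.9,
                           buffer_radius_m = 500,
                           n_pc_axes = 4,
                           months = MONTH_LABELS,
                           age_classes = AGE_CLASSES,
                           mcmc = list(),
                           priors = list(),
                           min_activity_n = 10,
                           min_staying_n = 10) {
  mcmc_defaults <- list(iterations = 50000L, burn_in = 10000L,
                        thin = 20L, chains = 3L, seed = 1L)
  prior_defaults <- list(alpha_low = -3, alpha_high = 3,
                         catchability_low = 0, catchability_high = 1,
                         dispersion_scale = 5, staying_sd = 10)
  mcmc <- utils::modifyList(mcmc_defaults, as.list(mcmc))
  priors <- utils::modifyList(prior_defaults, as.list(priors))

  assert_scalar_number(focal_side_m, "focal_side_m", 0, allow_zero = FALSE)
  assert_scalar_number(n_pc_axes, "n_pc_axes", 1, allow_zero = FALSE)
  for (f in c("iterations", "burn_in", "thin", "chains", "seed")) {
    assert_scalar_number(mcmc[[f]], paste0("mcmc$", f), 0)
  }
  if (mcmc$iterations <= mcmc$burn_in) {
    stop_boarest("mcmc$iterations must exceed mcmc$burn_in.")
  }
  if (mcmc$thin < 1 || mcmc$chains < 1) {
    stop_boarest("mcmc$thin and mcmc$chains must be >= 1.")
  }
  if (priors$alpha_low >= priors$alpha_high) {
    stop_boarest("priors$alpha_low must be below priors$alpha_high.")
  }
  if (priors$catchability_low < 0 || priors$catchability_low >= priors$catchability_high ||
      priors$catchability_high > 1) {
    stop_boarest("catchability prior support must satisfy 0 <= low < high <= 1.")
  }
  if (anyDuplicated(months) > 0L) stop_boarest("months must be unique.")

  structure(list(focal_side_m = focal_side_m,
                 buffer_radius_m = buffer_radius_m,
                 n_pc_axes = as.integer(n_pc_axes),
                 months = as.character(months),
                 age_classes = as.character(age_classes),
                 mcmc = lapply(mcmc, function(x) if (is.numeric(x)) as.integer(x) else x),
                 priors = priors,
                 min_activity_n = min_activity_n,
                 min_staying_n = min_staying_n),
            class = "boarest_config")
}

#' Read a study configuration from a YAML file
#'
#' @param path Path to a YAML file whose top-level keys match the arguments
#'   of [boarest_config()]. Missing keys take the defaults.
#' @return A `boarest_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop_boarest(sprintf("Config file not found: %s", path))
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(boarest_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    warn(sprintf("Ignoring unknown config key(s): %s",
                 paste(unknown, collapse = ", ")))
    raw <- raw[intersect(names(raw), known)]
  }
  do.call(boarest_config, raw)
}

#' @export
print.boarest_config <- function(x, ...) {
  cat("<boarest_config>\n")
  cat(sprintf("  focal area: equilateral triangle, side %.2f m (%.4f m^2)\n",
              x$focal_side_m, focal_area_from_side(x$focal_side_m)$area_m2))
  cat(sprintf("  months: %s\n", paste(x$months, collapse = " ")))
  cat(sprintf("  PC axes: %d | age classes: %s\n",
              x$n_pc_axes, paste(x$age_classes, collapse = ", ")))
  cat(sprintf("  mcmc: %d iterations, %d burn-in, thin %d, %d chains\n",
              x$mcmc$iterations, x$mcmc$burn_in, x$mcmc$thin, x$mcmc$chains))
  cat(sprintf("  priors: alpha ~ U(%g, %g); catchability ~ U(%g, %g)\n",
              x$priors$alpha_low, x$priors$alpha_high,
              x$priors$catchability_low, x$priors$catchability_high))
  invisible(x)
}
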