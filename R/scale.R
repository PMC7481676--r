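# Up-scaling from the habitat model to 1 km^2 grid cells and management
# units, and the catch-effort link between unit density and harvest records.

#' Density of a 1 km^2 grid cell
#'
#' Applies the habitat model to a cell's PC scores (computed with the
#' camera-site standardisation, see [project_pca()]).
#'
#' @param alpha Habitat coefficient vector `c(alpha0, alpha1..)`.
#' @param pc_scores Cell PC scores: vector, or matrix/data frame with one
#'   row per cell.
#' @return Density per km^2.
#' @export
cell_density <- function(alpha, pc_scores) {
  habitat_density(alpha, pc_scores)
}

#' Forest-area-weighted management-unit density
#'
#' Unit density is the weighted average of its cells' densities with
#' weights equal to the forested area in each cell, reflecting that the
#' modelled habitat is forest.
#'
#' @param densities Cell densities (per km^2).
#' @param forest_area_km2 Non-negative weights, same length.
#' @return Weighted mean density per km^2.
#' @export
#' @examples
#' unit_density(c(10, 20, 40), c(1, 2, 1))  # 22.5
unit_density <- function(densities, forest_area_km2) {
  stopifnot(length(densities) == length(forest_area_km2))
  if (any(forest_area_km2 < 0)) stop_boarest("forest areas must be >= 0.")
  w <- sum(forest_area_km2)
  if (w <= 0) {
    stop_boarest("Unit has no forested area: no habitat under the model.")
  }
  sum(densities * forest_area_km2) / w
}

#' Expected catch under the catch-effort model
#'
#' The number of trapped individuals in a unit-month is Poisson with mean
#' proportional to trapping effort (active traps) and local density; the
#' proportionality constant is the trap catchability.
#'
#' @param catchability Catch rate per trap-month per animal km^-2, in `[0, 1]`.
#' @param n_traps Number of active traps during the month.
#' @param density Unit density, animals per km^2.
#' @return Poisson mean catch.
#' @export
#' @examples
#' expected_catch(0.01, 10, 25)  # 2.5
expected_catch <- function(catchability, n_traps, density) {
  if (any(catchability < 0 | catchability > 1)) {
    stop_boarest("catchability must lie in [0, 1].")
  }
  if (any(n_traps < 0)) stop_boarest("n_traps must be >= 0.")
  if (any(density < 0)) stop_boarest("density must be >= 0.")
  catchability * n_traps * density
}

#' Catchability posterior given unit densities
#'
#' Direct catch-effort estimation: with densities treated as known, the
#' Poisson harvest likelihood with a uniform prior gives catchability per
#' (month, trap type) a gamma posterior truncated to the prior support,
#' which is sampled exactly. Inside the joint model the same full
#' conditional is used with the *estimated* densities.
#'
#' @param harvest Harvest tibble (see [read_harvest()]).
#' @param unit_densities Tibble `unit_id`, `month`, `density` (per km^2).
#' @param config A [boarest_config()] (prior support).
#' @param n_draws Posterior sample size per parameter.
#' @param seed Integer seed.
#' @return Tibble: month, trap_type, posterior mean/median, 50% and 95%
#'   credible intervals.
#' @export
estimate_catchability <- function(harvest, unit_densities,
                                  config = boarest_config(),
                                  n_draws = 4000, seed = 1) {
  pri <- config$priors
  set.seed(seed)
  h <- dplyr::left_join(harvest, unit_densities, by = c("unit_id", "month"))
  if (any(is.na(h$density))) {
    stop_boarest("Some harvest rows have no matching unit density.")
  }
  h |>
    dplyr::summarise(shape = sum(.data$n_trapped) + 1,
                     rate = sum(.data$n_traps * .data$density),
                     .by = c("month", "trap_type")) |>
    purrr::pmap_dfr(function(month, trap_type, shape, rate) {
      draws <- if (rate <= 0) {
        runif(n_draws, pri$catchability_low, pri$catchability_high)
      } else {
        qgamma(runif(n_draws, pgamma(pri$catchability_low, shape, rate),
                     pgamma(pri$catchability_high, shape, rate)),
               shape, rate)
      }
      tibble::tibble(month = month, trap_type = trap_type,
                     mean = mean(draws), median = median(draws),
                     q25 = quantile(draws, 0.25), q75 = quantile(draws, 0.75),
                     q2.5 = quantile(draws, 0.025),
                     q97.5 = quantile(draws, 0.975))
    })
}
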