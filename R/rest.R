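# The REST observation model: passages through a fixed focal area, staying
# time, and active time determine density; a log-linear habitat model on
# principal-component scores maps landscape to expected passage counts.

M2_PER_KM2 <- 1e6

#' Focal area of the camera's scoring triangle
#'
#' The focal area is an equilateral triangle of known side length placed in
#' the camera's field of view; passages and staying times are scored inside
#' it.
#'
#' @param side_m Side length in metres.
#' @return List with `side_m` and `area_m2` = sqrt(3)/4 * side^2.
#' @export
#' @examples
#' focal_area_from_side(1.9)$area_m2  # ~1.5632 m^2
focal_area_from_side <- function(side_m) {
  assert_scalar_number(side_m, "side_m", 0, allow_zero = FALSE)
  list(side_m = side_m, area_m2 = sqrt(3) / 4 * side_m^2)
}

#' Point REST density estimate
#'
#' Density = (passages / focal area) x (mean staying time / active time),
#' reported per km^2. This is the deterministic backbone of the count
#' likelihood: it is linear in passages and staying time and inverse-linear
#' in focal area and active time.
#'
#' @param n_passages Number of passages through the focal area.
#' @param area_m2 Focal area in m^2.
#' @param mean_stay_s Expected staying time per passage, seconds.
#' @param active_time_s Active camera time, seconds (deployment x daily
#'   activity proportion).
#' @return Density in animals per km^2.
#' @export
#' @examples
#' rest_density_point(20, focal_area_from_side(1.9)$area_m2, 8, 1e6)
rest_density_point <- function(n_passages, area_m2, mean_stay_s, active_time_s) {
  assert_scalar_number(area_m2, "area_m2", 0, allow_zero = FALSE)
  assert_scalar_number(mean_stay_s, "mean_stay_s", 0, allow_zero = FALSE)
  assert_scalar_number(active_time_s, "active_time_s", 0, allow_zero = FALSE)
  if (any(n_passages < 0)) stop_boarest("n_passages must be >= 0.")
  n_passages / area_m2 * mean_stay_s / active_time_s * M2_PER_KM2
}

#' Density from habitat coefficients at given PC scores
#'
#' The log-linear habitat model: density (per km^2) is
#' `exp(alpha0 + sum_e alpha_e * PC_e)`. The intercept is the log average
#' density across environments and the slopes are the habitat-preference
#' coefficients.
#'
#' @param alpha Numeric vector `c(alpha0, alpha1, ..)`; length 1 + n axes.
#' @param pc_scores Numeric vector of PC scores (same axis count), or a
#'   matrix/data frame with one row per location.
#' @return Density per km^2 (vector when scores are a matrix).
#' @export
habitat_density <- function(alpha, pc_scores) {
  if (is.data.frame(pc_scores)) pc_scores <- as.matrix(pc_scores)
  if (is.matrix(pc_scores)) {
    if (ncol(pc_scores) != length(alpha) - 1L) {
      stop_boarest("pc_scores must have one column per slope coefficient.")
    }
    as.vector(exp(alpha[1L] + pc_scores %*% alpha[-1L]))
  } else {
    if (length(pc_scores) != length(alpha) - 1L) {
      stop_boarest("pc_scores must have one score per slope coefficient.")
    }
    exp(alpha[1L] + sum(alpha[-1L] * pc_scores))
  }
}

#' Expected passage count under the habitat REST model
#'
#' Inverts the point REST equation: a camera at a location with density
#' `D(alpha, PC)` per km^2 is expected to record
#' `D * 1e-6 * area_m2 * active_time_s / mean_stay_s` passages.
#'
#' @inheritParams rest_density_point
#' @inheritParams habitat_density
#' @return Expected passage count (positive real).
#' @export
expected_count <- function(alpha, pc_scores, area_m2, mean_stay_s, active_time_s) {
  assert_scalar_number(area_m2, "area_m2", 0, allow_zero = FALSE)
  assert_scalar_number(mean_stay_s, "mean_stay_s", 0, allow_zero = FALSE)
  if (any(active_time_s < 0)) stop_boarest("active_time_s must be >= 0.")
  habitat_density(alpha, pc_scores) / M2_PER_KM2 * area_m2 *
    active_time_s / mean_stay_s
}

#' Negative-binomial log-likelihood of passage counts
#'
#' Passage counts are overdispersed relative to Poisson; the gamma-Poisson
#' mixture (negative binomial) with mean `mu` and shape `k` has variance
#' `mu + mu^2/k` and recovers the Poisson as `k` grows.
#'
#' @param n Observed count(s), non-negative integers.
#' @param mu Expected count(s), > 0.
#' @param k Gamma-heterogeneity shape, > 0.
#' @return Sum of log pmf values.
#' @export
nb_loglik <- function(n, mu, k) {
  if (any(!is.finite(mu)) || any(mu <= 0)) stop_boarest("mu must be > 0.")
  if (!is.finite(k) || k <= 0) stop_boarest("k must be > 0.")
  if (any(n < 0) || any(n != round(n))) {
    stop_boarest("n must contain non-negative integers.")
  }
  sum(dnbinom(n, size = k, mu = mu, log = TRUE))
}
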