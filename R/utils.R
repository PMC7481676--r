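# Internal helpers shared across modules.

LANDSCAPE_CLASSES <- c("broadleaf", "conifer", "farmland",
                       "bamboo", "abandoned", "residential")

TRAP_TYPES <- c("box", "snare")

AGE_CLASSES <- c("adult", "juvenile")

# month labels; parameters are indexed by calendar month throughout
MONTH_LABELS <- month.abb

stop_boarest <- function(msg, class = "boarest_error") {
  abort(msg, class = c(class, "boarest_error"))
}

assert_scalar_number <- function(x, name, lower = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_boarest(sprintf("`%s` must be a single finite number.", name))
  }
  bound_ok <- if (allow_zero) x >= lower else x > lower
  if (!bound_ok) {
    stop_boarest(sprintf("`%s` must be %s %s.", name,
                         if (allow_zero) ">=" else ">", format(lower)))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_boarest(sprintf("%s is missing required column(s): %s.",
                         what, paste(missing, collapse = ", ")),
                 class = "boarest_format_error")
  }
  invisible(df)
}

# hours on [0, 24) <-> radians on [0, 2*pi)
hours_to_radians <- function(h) (h %% 24) / 24 * 2 * pi
radians_to_hours <- function(r) (r %% (2 * pi)) / (2 * pi) * 24

seconds_per_day <- function() 86400

#' Scale of the motivating field study
#'
#' The dimensions of the municipal wild boar study the model was designed
#' around: a 799.6 km^2 area surveyed by 180 camera traps (about one
#' camera per 4.4 km^2), gridded into 897 cells of 1 km^2 grouped in 33
#' management units, with monthly parameters over 12 months. The `"full"`
#' simulator preset mirrors these dimensions.
#'
#' @return One-row tibble with `total_area_km2`, `n_cameras`, `n_cells`,
#'   `n_units`, `n_months` and the derived `km2_per_camera`.
#' @export
study_scale <- function() {
  tibble::tibble(total_area_km2 = 799.6, n_cameras = 180L, n_cells = 897L,
                 n_units = 33L, n_months = 12L,
                 km2_per_camera = 799.6 / 180)
}
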