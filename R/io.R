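# CSV readers and writers for the five study tables. CSV (RFC 4180, UTF-8)
# is the single interchange format; timestamps are local-time ISO-8601.

fail_rows <- function(bad, what, msg) {
  if (length(bad) > 0L) {
    shown <- paste(head(bad, 10L), collapse = ", ")
    extra <- if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L) else ""
    stop_boarest(sprintf("%s: %s in row(s) %s%s.", what, msg, shown, extra),
                 class = "boarest_validation_error")
  }
}

read_table_checked <- function(path, col_types, what) {
  if (!file.exists(path)) {
    stop_boarest(sprintf("%s file not found: %s", what, path),
                 class = "boarest_format_error")
  }
  df <- readr::read_csv(path, col_types = col_types, progress = FALSE)
  assert_columns(df, names(col_types$cols), what)
  df[names(col_types$cols)]
}

#' Read and validate a camera detection table
#'
#' One row per passage through the focal area. `staying_time_s` may be empty
#' for passages whose staying time was not scored.
#'
#' @param path CSV with columns `camera_id`, `timestamp` (ISO-8601 local
#'   time), `age_class` (`adult`/`juvenile`), `staying_time_s` (seconds,
#'   optional per row).
#' @return A validated tibble with `timestamp` parsed to POSIXct and a
#'   derived `month` label column.
#' @export
read_detections <- function(path) {
  df <- read_table_checked(path, readr::cols(
    camera_id = readr::col_character(),
    timestamp = readr::col_character(),
    age_class = readr::col_character(),
    staying_time_s = readr::col_double()
  ), "detections")
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  fail_rows(which(is.na(ts)), "detections",
            "unparseable ISO-8601 timestamp")
  fail_rows(which(!df$age_class %in% AGE_CLASSES), "detections",
            sprintf("age_class not in {%s}", paste(AGE_CLASSES, collapse = ", ")))
  fail_rows(which(!is.na(df$staying_time_s) & df$staying_time_s <= 0),
            "detections", "staying_time_s must be > 0 when present")
  df$timestamp <- ts
  df$month <- MONTH_LABELS[as.POSIXlt(ts)$mon + 1L]
  tibble::as_tibble(df)
}

#' Write a detection table
#' @param detections Tibble as returned by [read_detections()] (the derived
#'   `month` column is dropped on write).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  out <- detections[c("camera_id", "timestamp", "age_class", "staying_time_s")]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and validate camera deployment periods
#'
#' @param path CSV with columns `camera_id`, `start`, `end` (ISO-8601).
#'   A camera may have several active periods.
#' @return Tibble with parsed POSIXct bounds and `effort_s`, the period
#'   length in seconds.
#' @export
read_deployments <- function(path) {
  df <- read_table_checked(path, readr::cols(
    camera_id = readr::col_character(),
    start = readr::col_character(),
    end = readr::col_character()
  ), "deployments")
  s <- as.POSIXct(df$start, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  e <- as.POSIXct(df$end, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  fail_rows(which(is.na(s) | is.na(e)), "deployments", "unparseable timestamp")
  fail_rows(which(e <= s), "deployments", "end must be after start")
  tibble::tibble(camera_id = df$camera_id, start = s, end = e,
                 effort_s = as.numeric(difftime(e, s, units = "secs")))
}

#' @rdname read_deployments
#' @param deployments Tibble of deployment periods.
#' @export
write_deployments <- function(deployments, path) {
  out <- tibble::tibble(camera_id = deployments$camera_id,
                        start = format(deployments$start, "%Y-%m-%dT%H:%M:%S"),
                        end = format(deployments$end, "%Y-%m-%dT%H:%M:%S"))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and validate a landscape composition table
#'
#' Percentages of the six land-use classes (broadleaf, conifer, farmland,
#' bamboo, abandoned, residential) per camera-site buffer or per 1 km^2 grid
#' cell. Percentages may sum to less than 100 (water and other classes absorb
#' the remainder) but never more.
#'
#' @param path CSV with columns `id` and one column per class.
#' @return Validated tibble.
#' @export
read_landscape <- function(path) {
  spec <- c(list(id = readr::col_character()),
            setNames(rep(list(readr::col_double()), 6L), LANDSCAPE_CLASSES))
  df <- read_table_checked(path, do.call(readr::cols, spec), "landscape")
  pct <- as.matrix(df[LANDSCAPE_CLASSES])
  fail_rows(which(apply(pct, 1L, function(r) any(!is.finite(r) | r < 0 | r > 100))),
            "landscape", "each percentage must lie in [0, 100]")
  fail_rows(which(rowSums(pct) > 100 + 1e-8), "landscape",
            "class percentages must sum to <= 100")
  tibble::as_tibble(df)
}

#' @rdname read_landscape
#' @param landscape Composition tibble.
#' @export
write_landscape <- function(landscape, path) {
  readr::write_csv(landscape[c("id", LANDSCAPE_CLASSES)], path, progress = FALSE)
  invisible(path)
}

#' Read and validate a monthly harvest table
#'
#' Municipal trapping records: number of active traps and trapped
#' individuals per management unit, month and trap type.
#'
#' @param path CSV with columns `unit_id`, `month` (three-letter label),
#'   `trap_type` (`box`/`snare`), `n_traps`, `n_trapped`.
#' @return Validated tibble.
#' @export
read_harvest <- function(path) {
  df <- read_table_checked(path, readr::cols(
    unit_id = readr::col_character(),
    month = readr::col_character(),
    trap_type = readr::col_character(),
    n_traps = readr::col_double(),
    n_trapped = readr::col_double()
  ), "harvest")
  fail_rows(which(!df$trap_type %in% TRAP_TYPES), "harvest",
            sprintf("trap_type must be one of {%s}",
                    paste(TRAP_TYPES, collapse = ", ")))
  fail_rows(which(!df$month %in% MONTH_LABELS), "harvest",
            "month must be a three-letter month label")
  int_ok <- function(x) is.finite(x) & x >= 0 & x == round(x)
  fail_rows(which(!int_ok(df$n_traps)), "harvest",
            "n_traps must be a non-negative integer")
  fail_rows(which(!int_ok(df$n_trapped)), "harvest",
            "n_trapped must be a non-negative integer")
  fail_rows(which(df$n_traps == 0 & df$n_trapped > 0), "harvest",
            "n_trapped must be 0 where n_traps is 0")
  df$n_traps <- as.integer(df$n_traps)
  df$n_trapped <- as.integer(df$n_trapped)
  tibble::as_tibble(df)
}

#' @rdname read_harvest
#' @param harvest Harvest tibble.
#' @export
write_harvest <- function(harvest, path) {
  readr::write_csv(
    harvest[c("unit_id", "month", "trap_type", "n_traps", "n_trapped")],
    path, progress = FALSE)
  invisible(path)
}

#' Read and validate the grid-cell to management-unit map
#'
#' @param path CSV with columns `cell_id`, `unit_id`, `forest_area_km2`
#'   (forested area within the 1 km^2 cell).
#' @return Validated tibble; each cell maps to exactly one unit.
#' @export
read_units <- function(path) {
  df <- read_table_checked(path, readr::cols(
    cell_id = readr::col_character(),
    unit_id = readr::col_character(),
    forest_area_km2 = readr::col_double()
  ), "units")
  fail_rows(which(!is.finite(df$forest_area_km2) |
                    df$forest_area_km2 < 0 | df$forest_area_km2 > 1),
            "units", "forest_area_km2 must lie in [0, 1] for a 1 km^2 cell")
  dup <- df$cell_id[duplicated(df$cell_id)]
  if (length(dup) > 0L) {
    stop_boarest(sprintf("units: cell(s) mapped to more than one unit: %s.",
                         paste(unique(head(dup, 5L)), collapse = ", ")),
                 class = "boarest_validation_error")
  }
  tibble::as_tibble(df)
}

#' @rdname read_units
#' @param units Unit-map tibble.
#' @export
write_units <- function(units, path) {
  readr::write_csv(units[c("cell_id", "unit_id", "forest_area_km2")],
                   path, progress = FALSE)
  invisible(path)
}
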