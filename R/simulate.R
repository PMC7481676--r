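# Generative simulator: complete synthetic camera + harvest studies drawn
# from the model's own statistical structure (log-linear habitat densities
# on PCA scores, negative-binomial passage counts, parametric staying
# times, von Mises circadian activity, Poisson catch-effort harvest) with
# known ground truth. This is the principal testing surface: fitting a
# simulated study must recover its truth.

dirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3L)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2L] > 0 || log(c0 / u[2L]) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u[3L] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out %% (2 * pi)
}

#' Simulate landscape compositions and the management-unit map
#'
#' Camera-site and grid-cell compositions are drawn from a two-component
#' Dirichlet mixture: a forest-dominated archetype (cameras are placed in
#' forests) and a mosaic archetype mixing farmland, abandoned fields and
#' residential area. A few percent of each location is left to
#' water/other, so class percentages sum to slightly under 100. Cells are
#' partitioned into contiguous runs of roughly equal size as management
#' units; forested area per 1 km^2 cell is the broadleaf + conifer + bamboo
#' fraction.
#'
#' @param n_sites,n_cells,n_units Numbers of camera sites, 1 km^2 grid
#'   cells and management units (defaults mirror the study scale
#'   180/897/33).
#' @param seed Integer seed.
#' @param p_forest_site,p_forest_cell Mixture weight of the
#'   forest-dominated archetype for sites and cells.
#' @return List of tibbles: `sites` (id + class percentages), `cells`
#'   (likewise) and `units` (cell_id, unit_id, forest_area_km2).
#' @export
simulate_landscape <- function(n_sites = 180, n_cells = 897, n_units = 33,
                               seed = 1, p_forest_site = 0.85,
                               p_forest_cell = 0.55) {
  if (n_units > n_cells) stop_boarest("n_units must not exceed n_cells.")
  stopifnot(n_sites >= 1, n_cells >= 1, n_units >= 1)
  set.seed(seed)
  forest_alpha <- c(broadleaf = 9, conifer = 6, farmland = 1.2,
                    bamboo = 1.5, abandoned = 1.0, residential = 0.5)
  mosaic_alpha <- c(broadleaf = 2.5, conifer = 1.5, farmland = 6,
                    bamboo = 0.8, abandoned = 2.5, residential = 2.2)
  draw_comp <- function(n, p_forest) {
    comp <- t(vapply(seq_len(n), function(i) {
      a <- if (runif(1L) < p_forest) forest_alpha else mosaic_alpha
      dirichlet1(a) * runif(1L, 92, 99)   # remainder: water / other
    }, numeric(6L)))
    colnames(comp) <- LANDSCAPE_CLASSES
    tibble::as_tibble(comp)
  }
  sites <- dplyr::bind_cols(
    tibble::tibble(id = sprintf("cam%03d", seq_len(n_sites))),
    draw_comp(n_sites, p_forest_site))
  cells <- dplyr::bind_cols(
    tibble::tibble(id = sprintf("cell%04d", seq_len(n_cells))),
    draw_comp(n_cells, p_forest_cell))
  unit_of <- as.integer(cut(seq_len(n_cells), breaks = n_units, labels = FALSE))
  units <- tibble::tibble(
    cell_id = cells$id,
    unit_id = sprintf("u%02d", unit_of),
    forest_area_km2 = rowSums(cells[c("broadleaf", "conifer", "bamboo")]) / 100)
  list(sites = sites, cells = cells, units = units)
}

#' Ground-truth parameter bundle for a simulated study
#'
#' Defaults describe a plausible boar population: adult densities around
#' 5-10 per km^2 with mild seasonality, moderate habitat effects on the
#' four landscape axes, overdispersed passage counts (k ~ 1.5), lognormal
#' staying times with mean ~10 s, nocturnal activity (von Mises
#' concentration 1.5, peak 22:00, activity level ~0.37), and box/snare
#' catchabilities 0.02 and 0.012 (a ~1.7x box/snare ratio).
#'
#' @param months Month labels simulated.
#' @param juvenile_months Months in which juveniles are present (piglets
#'   are seasonal; empty vector for adults only).
#' @param seed Seed for the habitat-slope draws.
#' @param alpha0_adult,alpha0_juvenile Log mean density (per km^2).
#' @param k_adult,k_juvenile Negative-binomial shapes.
#' @param stay_meanlog_adult,stay_meanlog_juvenile,stay_sdlog Lognormal
#'   staying-time parameters (seconds scale).
#' @param activity_kappa,activity_peak_h Circadian von Mises parameters.
#' @param c_box,c_snare True catchabilities per trap-month per animal km^-2.
#' @return A `boarest_truth` list.
#' @export
simulate_truth <- function(months = MONTH_LABELS,
                           juvenile_months = c("Jun", "Jul", "Aug", "Sep", "Oct"),
                           seed = 1,
                           alpha0_adult = 1.9, alpha0_juvenile = 1.5,
                           k_adult = 1.5, k_juvenile = 1.2,
                           stay_meanlog_adult = 2.0,
                           stay_meanlog_juvenile = 1.7,
                           stay_sdlog = 0.8,
                           activity_kappa = 1.5, activity_peak_h = 22,
                           c_box = 0.02, c_snare = 0.012) {
  set.seed(seed)
  juvenile_months <- intersect(juvenile_months, months)
  combos <- dplyr::bind_rows(
    tibble::tibble(month = months, age_class = "adult"),
    tibble::tibble(month = juvenile_months, age_class = "juvenile"))
  season <- 0.3 * sin(2 * pi * (match(combos$month, MONTH_LABELS) - 1) / 12)
  alpha <- purrr::map2(combos$age_class, season, function(a, s) {
    base <- if (a == "adult") alpha0_adult else alpha0_juvenile
    c(base + s, round(runif(4, -0.5, 0.5), 2))
  })
  truth <- list(
    months = months, juvenile_months = juvenile_months,
    combos = combos, alpha = alpha,
    k = ifelse(combos$age_class == "adult", k_adult, k_juvenile),
    stay_family = "lognormal",
    stay_params = purrr::map(combos$age_class, function(a) {
      c(meanlog = if (a == "adult") stay_meanlog_adult else stay_meanlog_juvenile,
        sdlog = stay_sdlog)
    }),
    activity_kappa = activity_kappa,
    activity_peak_h = activity_peak_h,
    activity_proportion = besselI(activity_kappa, 0, expon.scaled = TRUE),
    catchability = c(box = c_box, snare = c_snare))
  class(truth) <- "boarest_truth"
  truth
}

truth_block <- function(truth, month, age_class) {
  i <- which(truth$combos$month == month & truth$combos$age_class == age_class)
  if (length(i) != 1L) {
    stop_boarest(sprintf("No truth parameters for %s/%s.", month, age_class))
  }
  i
}

month_start <- function(month, year = 2023) {
  as.POSIXct(sprintf("%d-%02d-01 00:00:00", year, match(month, MONTH_LABELS)),
             tz = "UTC")
}

month_length_s <- function(month, year = 2023) {
  m <- match(month, MONTH_LABELS)
  nxt <- if (m == 12L) c(year + 1L, 1L) else c(year, m + 1L)
  as.numeric(difftime(
    as.POSIXct(sprintf("%d-%02d-01", nxt[1L], nxt[2L]), tz = "UTC"),
    month_start(month, year), units = "secs"))
}

#' Simulate one month of camera data
#'
#' For each camera: the expected passage count follows the habitat REST
#' model at the camera's PC scores (with the true staying-time mean and
#' activity level in the denominator), the realised count is negative
#' binomial, staying times are drawn from the true family, and detection
#' timestamps combine a uniform day with a von Mises time of day.
#'
#' @param truth A `boarest_truth`.
#' @param site_scores Tibble `id`, `PC1..PC4` for the cameras.
#' @param month Month label.
#' @param age_class `"adult"` or `"juvenile"`.
#' @param deployment_s Per-camera deployment seconds for the month
#'   (recycled; default the full month).
#' @param focal A focal area from [focal_area_from_side()].
#' @param seed Integer seed.
#' @param stay_measured Max passages per month whose staying time is
#'   "measured with a stopwatch" (the rest get missing staying times).
#' @param year Calendar year used for timestamps.
#' @return List: `detections` slice and `counts` (one row per camera).
#' @export
simulate_camera_data <- function(truth, site_scores, month, age_class,
                                 deployment_s = NULL,
                                 focal = focal_area_from_side(1.9),
                                 seed = 1, stay_measured = 60,
                                 year = 2023) {
  i <- truth_block(truth, month, age_class)
  set.seed(seed)
  n_cam <- nrow(site_scores)
  deployment_s <- rep_len(deployment_s %||% month_length_s(month, year), n_cam)
  stay_mean <- exp(truth$stay_params[[i]]["meanlog"] +
                     truth$stay_params[[i]]["sdlog"]^2 / 2)
  pc <- as.matrix(site_scores[paste0("PC", 1:4)])
  mu <- expected_count(truth$alpha[[i]], pc, focal$area_m2, stay_mean,
                       deployment_s * truth$activity_proportion)
  n <- ifelse(mu > 0, rnbinom(n_cam, size = truth$k[i], mu = pmax(mu, 1e-12)), 0L)
  n[mu == 0] <- 0L

  det <- purrr::map_dfr(seq_len(n_cam), function(ci) {
    if (n[ci] == 0L) return(NULL)
    tod <- rvonmises(n[ci], hours_to_radians(truth$activity_peak_h),
                     truth$activity_kappa)
    n_days <- month_length_s(month, year) %/% seconds_per_day()
    ts <- month_start(month, year) +
      (sample.int(n_days, n[ci], replace = TRUE) - 1L) * seconds_per_day() +
      radians_to_hours(tod) * 3600
    tibble::tibble(camera_id = site_scores$id[ci], timestamp = ts,
                   age_class = age_class,
                   staying_time_s = rlnorm(n[ci],
                                           truth$stay_params[[i]]["meanlog"],
                                           truth$stay_params[[i]]["sdlog"]))
  })
  if (nrow(det) > stay_measured) {
    unmeasured <- sample(nrow(det), nrow(det) - stay_measured)
    det$staying_time_s[unmeasured] <- NA_real_
  }
  det$month <- month
  counts <- tibble::tibble(camera_id = site_scores$id, month = month,
                           age_class = age_class, n_passages = as.integer(n),
                           deployment_s = deployment_s)
  list(detections = det, counts = dplyr::bind_cols(counts,
                                                   tibble::as_tibble(pc)))
}

#' Simulate monthly harvest records
#'
#' Trap counts per unit-month-type are negative binomial (municipal effort
#' is patchy); catches are Poisson with mean catchability x traps x unit
#' density.
#'
#' @param truth A `boarest_truth`.
#' @param unit_densities Tibble `unit_id`, `month`, `density` (summed over
#'   age classes present).
#' @param seed Integer seed.
#' @param mean_traps,traps_size Negative-binomial mean and shape of the
#'   trap allocation per unit-month-type.
#' @param trap_table Optional tibble `unit_id`, `month`, `trap_type`,
#'   `n_traps` overriding the random allocation.
#' @return Harvest tibble (unit_id, month, trap_type, n_traps, n_trapped).
#' @export
simulate_harvest <- function(truth, unit_densities, seed = 1,
                             mean_traps = 30, traps_size = 5,
                             trap_table = NULL) {
  set.seed(seed)
  grid <- tidyr::expand_grid(
    dplyr::distinct(unit_densities, .data$unit_id, .data$month),
    trap_type = TRAP_TYPES)
  grid <- dplyr::left_join(grid, unit_densities, by = c("unit_id", "month"))
  if (is.null(trap_table)) {
    grid$n_traps <- rnbinom(nrow(grid), size = traps_size, mu = mean_traps)
  } else {
    grid <- dplyr::left_join(
      dplyr::select(grid, -dplyr::any_of("n_traps")), trap_table,
      by = c("unit_id", "month", "trap_type"))
    if (any(is.na(grid$n_traps)) || any(grid$n_traps < 0)) {
      stop_boarest("trap_table must cover every unit/month/type with n_traps >= 0.")
    }
  }
  lambda <- expected_catch(truth$catchability[grid$trap_type],
                           grid$n_traps, grid$density)
  grid$n_trapped <- rpois(nrow(grid), lambda)
  dplyr::select(grid, "unit_id", "month", "trap_type", "n_traps", "n_trapped")
}

#' Simulate a complete synthetic study
#'
#' Chains the landscape, camera and harvest generators into the full input
#' bundle the joint model consumes, with the ground truth attached. The
#' `"full"` preset mirrors the motivating study's scale (180 cameras, 897
#' cells, 33 units, 12 months); `"small"` (30 cameras, 100 cells, 6 units,
#' 3 months) keeps test runs fast.
#'
#' @param preset `"small"` or `"full"`, or `NULL` to use the explicit
#'   size arguments.
#' @param seed Integer seed driving every random draw.
#' @param n_sites,n_cells,n_units,months,juvenile_months Study dimensions.
#' @param effort_multiplier Scales every camera's deployment time (e.g. 2
#'   doubles camera effort).
#' @param stay_measured Staying times scored per month and age class
#'   (about 50 videos per month in the motivating protocol).
#' @param config A [boarest_config()].
#' @param truth Optionally a pre-built [simulate_truth()] bundle.
#' @return A `boarest_study` list: `detections`, `deployments`, `counts`,
#'   `sites`, `cells`, `units`, `harvest`, `basis`, `cell_scores`,
#'   `truth`, `config`.
#' @export
simulate_study <- function(preset = "small", seed = 1,
                           n_sites = NULL, n_cells = NULL, n_units = NULL,
                           months = NULL, juvenile_months = NULL,
                           effort_multiplier = 1, stay_measured = 60,
                           config = NULL, truth = NULL) {
  dims <- switch(preset %||% "custom",
    small = list(n_sites = 30, n_cells = 100, n_units = 6,
                 months = c("Jun", "Jul", "Aug"),
                 juvenile_months = c("Jun", "Jul")),
    full = list(n_sites = 180, n_cells = 897, n_units = 33,
                months = MONTH_LABELS,
                juvenile_months = c("Jun", "Jul", "Aug", "Sep", "Oct")),
    custom = list())
  n_sites <- n_sites %||% dims$n_sites
  n_cells <- n_cells %||% dims$n_cells
  n_units <- n_units %||% dims$n_units
  months <- months %||% dims$months
  juvenile_months <- juvenile_months %||% dims$juvenile_months
  config <- config %||% boarest_config(months = months)

  landscape <- simulate_landscape(n_sites, n_cells, n_units, seed = seed)
  basis <- fit_pca(landscape$sites, n_axes = config$n_pc_axes)
  cell_scores <- project_pca(basis, landscape$cells)
  truth <- truth %||% simulate_truth(months = months,
                                     juvenile_months = juvenile_months,
                                     seed = seed + 7L)
  focal <- focal_area_from_side(config$focal_side_m)
  year <- 2023

  sims <- purrr::pmap(truth$combos, function(month, age_class) {
    simulate_camera_data(
      truth, basis$site_scores, month, age_class,
      deployment_s = month_length_s(month, year) * effort_multiplier,
      focal = focal, stay_measured = stay_measured,
      seed = seed + 131L * truth_block(truth, month, age_class),
      year = year)
  })
  detections <- purrr::map_dfr(sims, "detections")
  counts <- purrr::map_dfr(sims, "counts")

  deployments <- purrr::map_dfr(months, function(m) {
    tibble::tibble(camera_id = landscape$sites$id,
                   start = month_start(m, year),
                   end = month_start(m, year) + month_length_s(m, year),
                   effort_s = month_length_s(m, year) * effort_multiplier)
  })

  # true unit densities (ages summed) -> harvest
  cellsD <- purrr::map_dfr(seq_len(nrow(truth$combos)), function(i) {
    tibble::tibble(cell_id = cell_scores$id,
                   month = truth$combos$month[i],
                   density = cell_density(truth$alpha[[i]],
                                          cell_scores[paste0("PC", 1:4)]))
  }) |>
    dplyr::summarise(density = sum(.data$density),
                     .by = c("cell_id", "month")) |>
    dplyr::left_join(landscape$units, by = "cell_id")
  unitD <- cellsD |>
    dplyr::summarise(density = unit_density(.data$density, .data$forest_area_km2),
                     .by = c("unit_id", "month"))
  harvest <- simulate_harvest(truth, unitD, seed = seed + 17L)

  structure(list(detections = detections, deployments = deployments,
                 counts = counts, sites = landscape$sites,
                 cells = landscape$cells, units = landscape$units,
                 harvest = harvest, basis = basis,
                 cell_scores = cell_scores, unit_density_true = unitD,
                 truth = truth, config = config, seed = seed),
            class = "boarest_study")
}

#' Write a simulated study to a directory of CSV files
#'
#' Emits the six interchange files (`detections.csv`, `deployments.csv`,
#' `landscape_sites.csv`, `landscape_cells.csv`, `harvest.csv`,
#' `units.csv`) plus `truth.yaml` with the generating parameters.
#'
#' @param study A `boarest_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_detections(study$detections, file.path(dir, "detections.csv"))
  write_deployments(study$deployments, file.path(dir, "deployments.csv"))
  write_landscape(study$sites, file.path(dir, "landscape_sites.csv"))
  write_landscape(study$cells, file.path(dir, "landscape_cells.csv"))
  write_harvest(study$harvest, file.path(dir, "harvest.csv"))
  write_units(study$units, file.path(dir, "units.csv"))
  truth <- study$truth
  yaml::write_yaml(list(
    months = truth$months, juvenile_months = truth$juvenile_months,
    alpha = purrr::map2(seq_len(nrow(truth$combos)), truth$alpha,
                        function(i, a) list(month = truth$combos$month[i],
                                            age_class = truth$combos$age_class[i],
                                            alpha = as.numeric(a))),
    k = as.numeric(truth$k), stay_family = truth$stay_family,
    activity_proportion = truth$activity_proportion,
    catchability = as.list(truth$catchability)),
    file.path(dir, "truth.yaml"))
  invisible(dir)
}
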