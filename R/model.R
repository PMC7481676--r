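# The joint hierarchical model: negative-binomial passage counts under the
# habitat REST model, parametric staying times, and Poisson catch-effort
# harvest, sharing the habitat coefficients across the camera and
# management-unit scales. Sampled by blocked adaptive Metropolis-within-
# Gibbs with an exact truncated-gamma Gibbs step for catchability.

combo_key <- function(month, age_class) paste(month, age_class, sep = ".")

#' Assemble the joint data bundle from a study
#'
#' Extracts from a simulated (or file-loaded) study the pieces the joint
#' model consumes: passage counts with PC scores, measured staying times,
#' plug-in activity levels, grid cells with scores/unit map, and harvest.
#'
#' @param study A `boarest_study` from [simulate_study()], or a directory
#'   containing the six interchange CSV files.
#' @param config A [boarest_config()]; defaults to the study's own.
#' @return List with elements `counts`, `stays`, `activity`, `cells`,
#'   `harvest`.
#' @export
prepare_joint_data <- function(study, config = NULL) {
  if (is.character(study)) {
    dir <- study
    detections <- read_detections(file.path(dir, "detections.csv"))
    deployments <- read_deployments(file.path(dir, "deployments.csv"))
    sites <- read_landscape(file.path(dir, "landscape_sites.csv"))
    cells <- read_landscape(file.path(dir, "landscape_cells.csv"))
    harvest <- read_harvest(file.path(dir, "harvest.csv"))
    units <- read_units(file.path(dir, "units.csv"))
    config <- config %||%
      boarest_config(months = intersect(MONTH_LABELS,
                                        unique(deployments_month(deployments)$month)))
    basis <- fit_pca(sites, n_axes = config$n_pc_axes)
    counts <- build_counts(detections, deployments, basis$site_scores, config)
    cell_scores <- project_pca(basis, cells)
    study <- list(detections = detections, counts = counts,
                  harvest = harvest, cell_scores = cell_scores,
                  units = units, config = config, basis = basis)
  }
  config <- config %||% study$config
  stays <- study$detections |>
    dplyr::filter(!is.na(.data$staying_time_s)) |>
    dplyr::select("month", "age_class", "staying_time_s", "camera_id")
  # age classes are modelled only in months with enough measured staying
  # times (juvenile staying time is typically measurable only around the
  # birth season)
  ok <- stays |>
    dplyr::count(.data$month, .data$age_class) |>
    dplyr::filter(.data$n >= min(config$min_staying_n, 10))
  dropped <- dplyr::anti_join(
    dplyr::distinct(study$counts, .data$month, .data$age_class), ok,
    by = c("month", "age_class"))
  if (nrow(dropped) > 0L) {
    inform(sprintf("Dropping month/age combinations with too few measured staying times: %s",
                   paste(combo_key(dropped$month, dropped$age_class),
                         collapse = ", ")))
  }
  counts <- dplyr::semi_join(study$counts, ok, by = c("month", "age_class"))
  activity <- estimate_activity(study$detections, config) |>
    dplyr::filter(!is.na(.data$proportion))
  cells <- dplyr::left_join(study$units,
                            dplyr::rename(study$cell_scores, cell_id = "id"),
                            by = "cell_id")
  list(counts = counts, stays = stays, activity = activity,
       cells = cells, harvest = study$harvest, config = config)
}

deployments_month <- function(deployments) {
  # split each active period at calendar-month boundaries and sum effort
  purrr::pmap_dfr(deployments[c("camera_id", "start", "end")],
                  function(camera_id, start, end) {
    cur <- start
    out <- list()
    while (cur < end) {
      lt <- as.POSIXlt(cur)
      nxt_month <- as.POSIXct(sprintf("%d-%02d-01", lt$year + 1900 +
                                        (lt$mon == 11L),
                                      (lt$mon + 1L) %% 12L + 1L), tz = "UTC")
      seg_end <- min(end, nxt_month)
      out[[length(out) + 1L]] <- tibble::tibble(
        camera_id = camera_id, month = MONTH_LABELS[lt$mon + 1L],
        effort_s = as.numeric(difftime(seg_end, cur, units = "secs")))
      cur <- seg_end
    }
    dplyr::bind_rows(out)
  }) |>
    dplyr::summarise(effort_s = sum(.data$effort_s),
                     .by = c("camera_id", "month"))
}

#' Passage counts per camera-month-age with covariates
#'
#' Tallies detections into the count table the REST likelihood uses,
#' attaching per-month deployment effort and the camera's PC scores.
#' Camera-months with zero deployment are dropped (they carry no
#' likelihood information).
#'
#' @param detections Detection tibble.
#' @param deployments Deployment tibble.
#' @param site_scores Tibble `id`, `PC1..` from [fit_pca()].
#' @param config A [boarest_config()].
#' @return Count tibble: camera_id, month, age_class, n_passages,
#'   deployment_s, PC scores.
#' @export
build_counts <- function(detections, deployments, site_scores,
                         config = boarest_config()) {
  effort <- deployments_month(deployments)
  tallies <- detections |>
    dplyr::count(.data$camera_id, .data$month, .data$age_class,
                 name = "n_passages")
  grid <- tidyr::expand_grid(
    effort,
    age_class = sort(unique(detections$age_class))) |>
    dplyr::filter(.data$month %in% config$months, .data$effort_s > 0)
  out <- grid |>
    dplyr::left_join(tallies, by = c("camera_id", "month", "age_class")) |>
    dplyr::mutate(n_passages = dplyr::coalesce(.data$n_passages, 0L),
                  deployment_s = .data$effort_s) |>
    dplyr::select(-"effort_s") |>
    dplyr::left_join(dplyr::rename(site_scores, camera_id = "id"),
                     by = "camera_id")
  if (any(is.na(out[paste0("PC", seq_len(config$n_pc_axes))]))) {
    stop_boarest("Some cameras in the detections have no landscape scores.")
  }
  out
}

# half-Cauchy prior (scale A) on 1/sqrt(k), expressed on log k
lp_dispersion <- function(log_k, A) {
  s <- exp(-log_k / 2)
  dcauchy(s, 0, A, log = TRUE) + log(2) + log(s / 2)
}

#' Build the joint model
#'
#' Validates and indexes the data bundle and returns an object holding the
#' prepared likelihood blocks and a `log_posterior` closure. The posterior
#' combines: NB passage counts per camera-month-age with mean
#' `density(alpha, PC) * 1e-6 * focal area * active time / E[staying
#' time]`; the staying-time likelihood of the chosen family; Poisson
#' harvest counts with mean `catchability * traps * unit density` where
#' unit density is the forest-area-weighted mean of cell densities summed
#' over the age classes modelled that month; uniform priors on alpha and
#' catchability, half-Cauchy on the NB dispersion, normal priors on
#' staying-time parameters.
#'
#' @param data Bundle from [prepare_joint_data()].
#' @param config A [boarest_config()].
#' @param family Staying-time family used in the joint model (default
#'   lognormal, the family the WAIC sweep typically selects for boar).
#' @return A `boarest_model`.
#' @export
build_joint_model <- function(data, config = boarest_config(),
                              family = "lognormal") {
  fam <- stay_family(family)
  counts <- dplyr::filter(data$counts, .data$deployment_s > 0)
  if (any(counts$n_passages < 0)) stop_boarest("Negative passage count.")
  combos <- dplyr::distinct(counts, .data$month, .data$age_class) |>
    dplyr::arrange(match(.data$month, config$months), .data$age_class)
  if (!all(combos$month %in% config$months)) {
    stop_boarest("Counts contain months absent from the configuration.")
  }
  focal <- focal_area_from_side(config$focal_side_m)
  naxes <- config$n_pc_axes
  pc_cols <- paste0("PC", seq_len(naxes))

  cells <- data$cells
  assert_columns(cells, c("cell_id", "unit_id", "forest_area_km2", pc_cols),
                 "cells")
  cellX <- cbind(1, as.matrix(cells[pc_cols]))
  unit_ids <- sort(unique(cells$unit_id))
  U <- t(vapply(unit_ids, function(u) {
    w <- ifelse(cells$unit_id == u, cells$forest_area_km2, 0)
    if (sum(w) <= 0) {
      stop_boarest(sprintf("Unit %s has no forested area.", u))
    }
    w / sum(w)
  }, numeric(nrow(cells))))

  blocks <- purrr::pmap(combos, function(month, age_class) {
    key <- combo_key(month, age_class)
    rows <- counts[counts$month == month & counts$age_class == age_class, ]
    act <- data$activity[data$activity$month == month &
                           data$activity$age_class == age_class, ]
    if (nrow(act) != 1L || is.na(act$proportion)) {
      stop_boarest(sprintf("No activity estimate for %s; estimate or pool first.", key))
    }
    st <- data$stays[data$stays$month == month &
                       data$stays$age_class == age_class, ]
    if (nrow(st) < 2L) {
      stop_boarest(sprintf(
        "Fewer than 2 measured staying times for %s; pool months or drop the age class.", key))
    }
    list(key = key, month = month, age_class = age_class,
         n = rows$n_passages,
         X = cbind(1, as.matrix(rows[pc_cols])),
         log_off = log(1e-6 * focal$area_m2 * rows$deployment_s *
                         act$proportion),
         stays = st$staying_time_s,
         activity = act$proportion)
  })
  names(blocks) <- vapply(blocks, `[[`, character(1L), "key")

  harvest <- data$harvest
  harv <- NULL
  cat_combos <- NULL
  if (!is.null(harvest) && nrow(harvest) > 0L) {
    bad_m <- setdiff(unique(harvest$month), combos$month)
    if (length(bad_m) > 0L) {
      stop_boarest(sprintf(
        "Harvest month(s) %s have no density model (no camera data).",
        paste(bad_m, collapse = ", ")))
    }
    bad_u <- setdiff(unique(harvest$unit_id), unit_ids)
    if (length(bad_u) > 0L) {
      stop_boarest(sprintf("Harvest unit(s) %s missing from the cell map.",
                           paste(bad_u, collapse = ", ")))
    }
    harv <- harvest |>
      dplyr::mutate(u = match(.data$unit_id, unit_ids),
                    m = match(.data$month, unique(combos$month)),
                    t = match(.data$trap_type, TRAP_TYPES))
    cat_combos <- dplyr::distinct(harvest, .data$month, .data$trap_type) |>
      dplyr::arrange(match(.data$month, config$months), .data$trap_type)
  }

  model <- structure(list(
    blocks = blocks, combos = combos, family = family, fam = fam,
    cellX = cellX, U = U, unit_ids = unit_ids,
    months = unique(combos$month),
    harvest = harv, cat_combos = cat_combos,
    config = config, focal = focal), class = "boarest_model")

  model$log_posterior <- function(par) joint_lp(model, par)
  model
}

# Full log posterior at a structured parameter point:
# par$alpha  : named list (key -> numeric(1 + n_axes))
# par$log_k  : named numeric (key)
# par$stay   : named list (key -> family parameters, unconstrained scale)
# par$catchability : named numeric ("month.trap_type")
joint_lp <- function(model, par) {
  pri <- model$config$priors
  lp <- 0
  cellD <- list()
  for (b in model$blocks) {
    a <- par$alpha[[b$key]]
    if (any(a < pri$alpha_low) || any(a > pri$alpha_high)) return(-Inf)
    th <- par$stay[[b$key]]
    k <- exp(par$log_k[[b$key]])
    sm <- model$fam$mean(th)
    if (!is.finite(sm) || sm <= 0) return(-Inf)
    eta <- as.vector(b$X %*% a)
    lp <- lp + sum(dnbinom(b$n, size = k,
                           mu = exp(eta + b$log_off - log(sm)), log = TRUE)) +
      sum(model$fam$loglik(th, b$stays, 0)) +
      sum(dnorm(th, 0, pri$staying_sd, log = TRUE)) +
      lp_dispersion(par$log_k[[b$key]], pri$dispersion_scale)
    cellD[[b$key]] <- exp(as.vector(model$cellX %*% a))
  }
  if (!is.null(model$harvest)) {
    unitD <- matrix(0, length(model$unit_ids), length(model$months))
    for (b in model$blocks) {
      mi <- match(b$month, model$months)
      unitD[, mi] <- unitD[, mi] + as.vector(model$U %*% cellD[[b$key]])
    }
    cc <- par$catchability
    if (any(cc < pri$catchability_low) || any(cc > pri$catchability_high)) {
      return(-Inf)
    }
    h <- model$harvest
    lam <- cc[combo_key(h$month, h$trap_type)] * h$n_traps *
      unitD[cbind(h$u, h$m)]
    lp <- lp + sum(dpois(h$n_trapped, lam, log = TRUE))
  }
  lp
}

#' Sample the joint posterior
#'
#' Blocked adaptive Metropolis-within-Gibbs: each (month, age class) block
#' updates its habitat coefficients, NB dispersion and staying-time
#' parameters coordinate-wise with adaptive Gaussian random walks (hard
#' uniform bounds on the coefficients); catchability is drawn exactly from
#' its truncated-gamma full conditional. Burn-in is discarded and thinning
#' applied before draws are stored; derived unit densities are recorded
#' alongside the sampled parameters.
#'
#' @param model A `boarest_model`.
#' @param iterations,burn_in,thin,chains,seed MCMC settings; defaults come
#'   from the model's configuration.
#' @return A `boarest_fit`: per-chain draw matrices, summary tibble with
#'   posterior mean/median, 50% and 95% credible intervals, and split-chain
#'   Rhat per quantity.
#' @export
run_mcmc <- function(model, iterations = NULL, burn_in = NULL, thin = NULL,
                     chains = NULL, seed = NULL) {
  stopifnot(inherits(model, "boarest_model"))
  mc <- model$config$mcmc
  iterations <- iterations %||% mc$iterations
  burn_in <- burn_in %||% mc$burn_in
  thin <- thin %||% mc$thin
  chains <- chains %||% mc$chains
  seed <- seed %||% mc$seed
  draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + 1000L * (ch - 1L))
    draws[[ch]] <- joint_chain(model, iterations, burn_in, thin)
  }
  finish_fit(model, draws,
             settings = list(iterations = iterations, burn_in = burn_in,
                             thin = thin, chains = chains, seed = seed))
}

joint_chain <- function(model, n_iter, burn_in, thin, batch = 50L) {
  pri <- model$config$priors
  fam <- model$fam
  B <- length(model$blocks)
  npar_st <- fam$npar
  n_units <- length(model$unit_ids)
  months <- model$months
  nM <- length(months)

  # --- initial state (dispersed; draw before touching caches) ---
  st <- vector("list", B)
  for (bi in seq_len(B)) {
    b <- model$blocks[[bi]]
    alpha <- c(runif(1, max(pri$alpha_low, -1), min(pri$alpha_high, 2.5)),
               runif(length(b$X[1, ]) - 1L, -0.4, 0.4))
    thst <- fam$init(b$stays) + rnorm(npar_st, 0, 0.1)
    st[[bi]] <- list(alpha = alpha, log_k = log(runif(1, 0.8, 2.5)),
                     thst = thst)
  }

  harv <- model$harvest
  has_harv <- !is.null(harv)
  if (has_harv) {
    hm <- split(seq_len(nrow(harv)), harv$m)   # harvest rows per month index
    cat_keys <- combo_key(model$cat_combos$month, model$cat_combos$trap_type)
    catch <- setNames(runif(length(cat_keys), pri$catchability_low,
                            pri$catchability_high), cat_keys)
    h_key <- combo_key(harv$month, harv$trap_type)
  }

  # --- caches ---
  eta <- vector("list", B); cellD <- vector("list", B)
  staymean <- numeric(B); nb_ll <- numeric(B); stay_ll <- numeric(B)
  unitD <- matrix(0, n_units, nM)
  m_of <- match(vapply(model$blocks, `[[`, character(1L), "month"), months)
  for (bi in seq_len(B)) {
    b <- model$blocks[[bi]]
    eta[[bi]] <- as.vector(b$X %*% st[[bi]]$alpha)
    cellD[[bi]] <- exp(as.vector(model$cellX %*% st[[bi]]$alpha))
    staymean[bi] <- fam$mean(st[[bi]]$thst)
    nb_ll[bi] <- sum(dnbinom(b$n, size = exp(st[[bi]]$log_k),
                             mu = exp(eta[[bi]] + b$log_off - log(staymean[bi])),
                             log = TRUE))
    stay_ll[bi] <- sum(fam$loglik(st[[bi]]$thst, b$stays, 0))
    unitD[, m_of[bi]] <- unitD[, m_of[bi]] +
      as.vector(model$U %*% cellD[[bi]])
  }
  harv_ll <- numeric(nM)
  calc_harv_ll <- function(mi, ucol) {
    if (!has_harv || is.null(hm[[as.character(mi)]])) return(0)
    idx <- hm[[as.character(mi)]]
    lam <- catch[h_key[idx]] * harv$n_traps[idx] * ucol[harv$u[idx]]
    sum(dpois(harv$n_trapped[idx], lam, log = TRUE))
  }
  if (has_harv) for (mi in seq_len(nM)) harv_ll[mi] <- calc_harv_ll(mi, unitD[, mi])

  # --- adaptive step sizes: per block, per coordinate ---
  d_block <- 1L + ncol(model$blocks[[1L]]$X) - 1L + 1L + npar_st  # alphas + logk + stay
  n_alpha <- ncol(model$blocks[[1L]]$X)
  ls <- matrix(-1, B, n_alpha + 1L + npar_st)
  acc <- matrix(0L, B, ncol(ls))

  kept_idx <- seq.int(burn_in + thin, n_iter, by = thin)
  par_names <- unlist(lapply(unname(model$blocks), function(b) {
    key <- sprintf("[%s,%s]", b$month, b$age_class)
    c(paste0("alpha", seq_len(n_alpha) - 1L, key), paste0("k", key),
      paste0("stay_", fam$par_names, key), paste0("stay_mean", key),
      paste0("mean_cell_density", key))
  }))
  if (has_harv) {
    par_names <- c(par_names, sprintf("catchability[%s,%s]",
                                      model$cat_combos$month,
                                      model$cat_combos$trap_type))
  }
  par_names <- c(par_names, as.vector(outer(model$unit_ids, months,
                                            function(u, m) sprintf("density[%s,%s]", u, m))))
  out <- matrix(NA_real_, length(kept_idx), length(par_names))
  colnames(out) <- par_names

  k_out <- 1L
  for (it in seq_len(n_iter)) {
    for (bi in seq_len(B)) {
      b <- model$blocks[[bi]]
      mi <- m_of[bi]
      # habitat coefficients
      for (j in seq_len(n_alpha)) {
        prop <- st[[bi]]$alpha[j] + exp(ls[bi, j]) * rnorm(1L)
        if (prop < pri$alpha_low || prop > pri$alpha_high) next
        delta <- prop - st[[bi]]$alpha[j]
        eta_new <- eta[[bi]] + delta * b$X[, j]
        nb_new <- sum(dnbinom(b$n, size = exp(st[[bi]]$log_k),
                              mu = exp(eta_new + b$log_off - log(staymean[bi])),
                              log = TRUE))
        cellD_new <- cellD[[bi]] * exp(delta * model$cellX[, j])
        ucol_new <- unitD[, mi] + as.vector(model$U %*% (cellD_new - cellD[[bi]]))
        harv_new <- calc_harv_ll(mi, ucol_new)
        if (log(runif(1L)) < (nb_new + harv_new) - (nb_ll[bi] + harv_ll[mi])) {
          st[[bi]]$alpha[j] <- prop
          eta[[bi]] <- eta_new; cellD[[bi]] <- cellD_new
          unitD[, mi] <- ucol_new
          nb_ll[bi] <- nb_new; harv_ll[mi] <- harv_new
          acc[bi, j] <- acc[bi, j] + 1L
        }
      }
      # NB dispersion
      jj <- n_alpha + 1L
      prop_lk <- st[[bi]]$log_k + exp(ls[bi, jj]) * rnorm(1L)
      nb_new <- sum(dnbinom(b$n, size = exp(prop_lk),
                            mu = exp(eta[[bi]] + b$log_off - log(staymean[bi])),
                            log = TRUE))
      logr <- nb_new - nb_ll[bi] +
        lp_dispersion(prop_lk, pri$dispersion_scale) -
        lp_dispersion(st[[bi]]$log_k, pri$dispersion_scale)
      if (is.finite(logr) && log(runif(1L)) < logr) {
        st[[bi]]$log_k <- prop_lk; nb_ll[bi] <- nb_new
        acc[bi, jj] <- acc[bi, jj] + 1L
      }
      # staying-time parameters (mean feeds the NB denominator)
      for (sj in seq_len(npar_st)) {
        jj <- n_alpha + 1L + sj
        th_new <- st[[bi]]$thst
        th_new[sj] <- th_new[sj] + exp(ls[bi, jj]) * rnorm(1L)
        sm_new <- fam$mean(th_new)
        if (!is.finite(sm_new) || sm_new <= 0) next
        nb_new <- sum(dnbinom(b$n, size = exp(st[[bi]]$log_k),
                              mu = exp(eta[[bi]] + b$log_off - log(sm_new)),
                              log = TRUE))
        stay_new <- sum(fam$loglik(th_new, b$stays, 0))
        logr <- (nb_new + stay_new) - (nb_ll[bi] + stay_ll[bi]) +
          dnorm(th_new[sj], 0, pri$staying_sd, log = TRUE) -
          dnorm(st[[bi]]$thst[sj], 0, pri$staying_sd, log = TRUE)
        if (is.finite(logr) && log(runif(1L)) < logr) {
          st[[bi]]$thst <- th_new; staymean[bi] <- sm_new
          nb_ll[bi] <- nb_new; stay_ll[bi] <- stay_new
          acc[bi, jj] <- acc[bi, jj] + 1L
        }
      }
    }
    # catchability: exact truncated-gamma Gibbs (uniform prior)
    if (has_harv) {
      for (ck in seq_along(catch)) {
        key <- names(catch)[ck]
        idx <- which(h_key == key)
        shape <- sum(harv$n_trapped[idx]) + 1
        rate <- sum(harv$n_traps[idx] * unitD[cbind(harv$u[idx], harv$m[idx])])
        if (rate <= 0) {
          catch[ck] <- runif(1L, pri$catchability_low, pri$catchability_high)
        } else {
          plo <- pgamma(pri$catchability_low, shape, rate)
          phi <- pgamma(pri$catchability_high, shape, rate)
          if (phi - plo > 1e-12) {
            catch[ck] <- qgamma(runif(1L, plo, phi), shape, rate)
          } else {
            catch[ck] <- min(max(shape / rate, pri$catchability_low),
                             pri$catchability_high)
          }
        }
      }
      for (mi in seq_len(nM)) harv_ll[mi] <- calc_harv_ll(mi, unitD[, mi])
    }
    # adapt during burn-in
    if (it <= burn_in && it %% batch == 0L) {
      delta <- min(0.1, 1 / sqrt(it / batch))
      ls <- ls + ifelse(acc / batch > 0.44, delta, -delta)
      acc[] <- 0L
    }
    if (k_out <= length(kept_idx) && it == kept_idx[k_out]) {
      row <- unlist(lapply(seq_len(B), function(bi) {
        c(st[[bi]]$alpha, exp(st[[bi]]$log_k), st[[bi]]$thst,
          staymean[bi], mean(cellD[[bi]]))
      }))
      if (has_harv) row <- c(row, catch)
      out[k_out, ] <- c(row, as.vector(unitD))
      k_out <- k_out + 1L
    }
  }
  out
}

finish_fit <- function(model, draws, settings) {
  all_draws <- do.call(rbind, draws)
  terms <- unname(colnames(all_draws))
  rh <- if (length(draws) >= 2L) {
    vapply(terms, function(tm) {
      rhat(vapply(draws, function(d) d[, tm], numeric(nrow(draws[[1L]]))))
    }, numeric(1L))
  } else setNames(rep(NA_real_, length(terms)), terms)
  qs <- t(apply(all_draws, 2L, quantile,
                probs = c(0.025, 0.25, 0.5, 0.75, 0.975)))
  summary <- tibble::tibble(
    term = terms,
    mean = unname(colMeans(all_draws)),
    sd = unname(apply(all_draws, 2L, sd)),
    q2.5 = qs[, 1L], q25 = qs[, 2L], median = qs[, 3L],
    q75 = qs[, 4L], q97.5 = qs[, 5L],
    rhat = unname(rh[terms]))
  structure(list(draws = draws, summary = summary, rhat = rh,
                 settings = settings, combos = model$combos,
                 family = model$family, months = model$months,
                 unit_ids = model$unit_ids,
                 cat_combos = model$cat_combos),
            class = "boarest_fit")
}

#' Fit the joint model to a study
#'
#' Convenience wrapper: prepares the data bundle, optionally selects the
#' staying-time family by a WAIC sweep over the four candidates (staged,
#' on the pooled measured staying times), builds the joint model and runs
#' the sampler.
#'
#' @param study A `boarest_study` or a data directory path.
#' @param config A [boarest_config()].
#' @param family Staying-time family, or `"auto"` for WAIC selection.
#' @param ... Passed to [run_mcmc()] (`iterations`, `burn_in`, `thin`,
#'   `chains`, `seed`).
#' @return A `boarest_fit`; when `family = "auto"` the WAIC comparison is
#'   attached as `$staying_selection`.
#' @export
fit_boarest <- function(study, config = NULL, family = "lognormal", ...) {
  data <- prepare_joint_data(study, config)
  config <- data$config
  selection <- NULL
  if (identical(family, "auto")) {
    sweep <- staying_time_sweep(data$stays$staying_time_s,
                                camera_ids = data$stays$camera_id,
                                config = config,
                                seed = config$mcmc$seed)
    family <- sweep$best$family
    selection <- sweep$comparison
  }
  model <- build_joint_model(data, config, family = family)
  fit <- run_mcmc(model, ...)
  fit$staying_selection <- selection
  fit
}

#' @export
print.boarest_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<boarest_fit> %d quantities, %d chains x %d draws (%s staying times)\n",
              g$n_terms, g$chains, g$draws_per_chain, x$family))
  cat(sprintf("  max Rhat = %.3f (%s)\n", g$max_rhat,
              if (isTRUE(g$converged)) "converged, < 1.1" else "NOT converged"))
  invisible(x)
}

#' @export
tidy.boarest_fit <- function(x, ...) x$summary

#' @export
glance.boarest_fit <- function(x, ...) {
  tibble::tibble(
    n_terms = nrow(x$summary),
    chains = x$settings$chains,
    draws_per_chain = nrow(x$draws[[1L]]),
    iterations = x$settings$iterations,
    max_rhat = max(x$rhat, na.rm = TRUE),
    converged = max(x$rhat, na.rm = TRUE) < 1.1)
}

term_group <- function(term) sub("\\[.*$", "", term)

#' Extract grouped posterior summaries from a fit
#'
#' @param fit A `boarest_fit`.
#' @param what One of `"density"` (management-unit densities),
#'   `"alpha"` (habitat coefficients), `"catchability"`,
#'   `"stay_mean"`, `"mean_cell_density"` or `"k"`.
#' @return Summary tibble with the bracket indices split into columns.
#' @export
fit_summary <- function(fit, what = c("density", "alpha", "catchability",
                                      "stay_mean", "mean_cell_density", "k")) {
  what <- match.arg(what)
  s <- fit$summary
  grp <- term_group(s$term)
  keep <- if (what == "alpha") grepl("^alpha[0-9]$", grp) else grp == what
  s <- s[keep, ]
  inside <- sub("^[^\\[]*\\[(.*)\\]$", "\\1", s$term)
  parts <- do.call(rbind, strsplit(inside, ","))
  lab <- switch(what,
    density = c("unit_id", "month"),
    catchability = c("month", "trap_type"),
    c("month", "age_class"))
  idx <- tibble::as_tibble(setNames(as.data.frame(parts,
                                                  stringsAsFactors = FALSE), lab))
  out <- dplyr::bind_cols(idx, s)
  if (what == "alpha") out$axis <- as.integer(sub("^alpha", "", grp[keep]))
  out
}

#' Plot posterior summaries of a joint fit
#'
#' @param object A `boarest_fit`.
#' @param what Quantity to plot (see [fit_summary()]). Whiskers show the
#'   50% credible interval, points the posterior median.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.boarest_fit <- function(object, what = "density", ...) {
  df <- fit_summary(object, what)
  df$month <- factor(df$month, levels = MONTH_LABELS)
  colour_var <- intersect(c("age_class", "trap_type", "unit_id"), names(df))[1L]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$month, y = .data$median,
                                        colour = .data[[colour_var]],
                                        group = .data[[colour_var]])) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = what)
  if ("axis" %in% names(df)) p <- p + ggplot2::facet_wrap(~axis)
  p
}
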