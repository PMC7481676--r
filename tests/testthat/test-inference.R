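make_point <- function(model, study) {
  # a fixed, valid parameter point assembled from the simulation truth
  par <- list(alpha = list(), log_k = c(), stay = list(), catchability = c())
  for (b in model$blocks) {
    i <- which(study$truth$combos$month == b$month &
                 study$truth$combos$age_class == b$age_class)
    par$alpha[[b$key]] <- study$truth$alpha[[i]]
    par$log_k[b$key] <- log(study$truth$k[i])
    par$stay[[b$key]] <- c(study$truth$stay_params[[i]]["meanlog"],
                           log(study$truth$stay_params[[i]]["sdlog"]))
  }
  if (!is.null(model$cat_combos)) {
    keys <- paste(model$cat_combos$month, model$cat_combos$trap_type, sep = ".")
    par$catchability <- setNames(
      study$truth$catchability[model$cat_combos$trap_type], keys)
  }
  par
}

test_that("the joint log posterior equals hand-summed components", {
  st <- fixture_study()
  d <- fixture_data()
  model <- build_joint_model(d, st$config)
  par <- make_point(model, st)

  # oracle: recompute every term with the package's likelihood primitives
  # and plain arithmetic, independently of the sampler's caching
  cfg <- st$config
  area <- focal_area_from_side(cfg$focal_side_m)$area_m2
  lp <- 0
  cellD_total <- list()
  for (b in model$blocks) {
    a <- par$alpha[[b$key]]
    th <- par$stay[[b$key]]
    sm <- exp(th[1] + exp(th[2])^2 / 2)
    mu <- vapply(seq_along(b$n), function(r) {
      expected_count(a, b$X[r, -1], area,
                     sm, exp(b$log_off[r]) / (1e-6 * area))
    }, numeric(1))
    lp <- lp + nb_loglik(b$n, mu, exp(par$log_k[b$key])) +
      sum(dlnorm(b$stays, th[1], exp(th[2]), log = TRUE)) +
      sum(dnorm(th, 0, cfg$priors$staying_sd, log = TRUE)) +
      boarest:::lp_dispersion(par$log_k[b$key], cfg$priors$dispersion_scale)
    cellD_total[[b$key]] <- cell_density(a, d$cells[paste0("PC", 1:4)])
  }
  harv <- d$harvest
  units <- split(seq_len(nrow(d$cells)), d$cells$unit_id)
  for (r in seq_len(nrow(harv))) {
    m <- harv$month[r]
    keys <- names(cellD_total)[startsWith(names(cellD_total), paste0(m, "."))]
    cd <- Reduce(`+`, cellD_total[keys])
    idx <- units[[harv$unit_id[r]]]
    D <- unit_density(cd[idx], d$cells$forest_area_km2[idx])
    lam <- expected_catch(par$catchability[paste(m, harv$trap_type[r],
                                                 sep = ".")],
                          harv$n_traps[r], D)
    lp <- lp + dpois(harv$n_trapped[r], lam, log = TRUE)
  }
  expect_equal(model$log_posterior(par), unname(lp), tolerance = 1e-8)
})

test_that("an empty harvest reduces the posterior to the REST-only model", {
  st <- fixture_study()
  d <- fixture_data()
  d_no_harv <- d
  d_no_harv$harvest <- NULL
  m_full <- build_joint_model(d, st$config)
  m_rest <- build_joint_model(d_no_harv, st$config)
  par <- make_point(m_full, st)
  harvest_terms <- m_full$log_posterior(par) - m_rest$log_posterior(par)
  # the difference is exactly the Poisson harvest log likelihood
  expect_true(is.finite(harvest_terms))
  par0 <- par
  par0$catchability[] <- 0
  zero_catch <- sum(dpois(d$harvest$n_trapped, 0, log = TRUE))
  expect_equal(m_full$log_posterior(par0) - m_rest$log_posterior(par0),
               zero_catch)
})

test_that("habitat coefficients outside the uniform prior support are impossible", {
  st <- fixture_study()
  model <- build_joint_model(fixture_data(), st$config)
  par <- make_point(model, st)
  par$alpha[[1]][2] <- 3.5
  expect_identical(model$log_posterior(par), -Inf)
  par <- make_point(model, st)
  par$catchability[1] <- 1.2
  expect_identical(model$log_posterior(par), -Inf)
})

test_that("harvest months without camera data are rejected", {
  st <- fixture_study()
  d <- fixture_data()
  d$harvest$month[1] <- "Dec"
  expect_error(build_joint_model(d, st$config), "no density model")
})

test_that("joint sampling is deterministic given the seed", {
  st <- fixture_study()
  model <- build_joint_model(fixture_data(), st$config)
  f1 <- run_mcmc(model, iterations = 120, burn_in = 40, thin = 4,
                 chains = 2, seed = 77)
  f2 <- run_mcmc(model, iterations = 120, burn_in = 40, thin = 4,
                 chains = 2, seed = 77)
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws[[1]]), 20)
})

test_that("posterior summaries carry 50% and 95% intervals and Rhat", {
  st <- fixture_study()
  model <- build_joint_model(fixture_data(), st$config)
  fit <- run_mcmc(model, iterations = 200, burn_in = 80, thin = 4,
                  chains = 2, seed = 3)
  s <- tidy(fit)
  expect_true(all(c("q25", "q75", "q2.5", "q97.5", "median", "rhat")
                  %in% names(s)))
  expect_true(all(s$q25 <= s$median & s$median <= s$q75))
  # the split-chain estimator can dip just below 1 (floor sqrt((n-1)/n)
  # at half-chain length n)
  n_half <- floor(nrow(fit$draws[[1]]) / 2)
  expect_true(all(s$rhat >= sqrt((n_half - 1) / n_half) - 1e-8, na.rm = TRUE))
  expect_s3_class(autoplot(fit, "density"), "ggplot")
  expect_s3_class(autoplot(fit, "alpha"), "ggplot")
})
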