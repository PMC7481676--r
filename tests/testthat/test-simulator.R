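test_that("simulated compositions are valid and reproducible", {
  l1 <- simulate_landscape(n_sites = 50, n_cells = 80, n_units = 5, seed = 42)
  l2 <- simulate_landscape(n_sites = 50, n_cells = 80, n_units = 5, seed = 42)
  expect_identical(l1, l2)
  for (tab in list(l1$sites, l1$cells)) {
    pct <- as.matrix(tab[-1])
    expect_true(all(pct >= 0 & pct <= 100))
    expect_true(all(rowSums(pct) <= 100))
  }
  expect_equal(dplyr::n_distinct(l1$units$unit_id), 5)
  expect_true(all(l1$units$forest_area_km2 >= 0 &
                    l1$units$forest_area_km2 <= 1))
  expect_error(simulate_landscape(10, 5, 8), "exceed")
})

test_that("four PCA axes capture most simulated landscape variation", {
  l <- simulate_landscape(n_sites = 500, n_cells = 10, n_units = 2, seed = 3)
  basis <- fit_pca(l$sites)
  expect_gt(sum(basis$explained[1:4]), 0.7)
})

test_that("simulated passage counts have the prescribed NB moments", {
  truth <- simulate_truth(months = "Jun", juvenile_months = character(0),
                          seed = 1, k_adult = 2)
  scores <- tibble::tibble(id = sprintf("c%04d", 1:5000),
                           PC1 = 0, PC2 = 0, PC3 = 0, PC4 = 0)
  # choose deployment so that mu is about 5
  i <- 1L
  stay_mean <- exp(truth$stay_params[[i]]["meanlog"] +
                     truth$stay_params[[i]]["sdlog"]^2 / 2)
  area <- focal_area_from_side(1.9)$area_m2
  mu_target <- 5
  dep <- mu_target * stay_mean * 1e6 /
    (exp(truth$alpha[[i]][1]) * area * truth$activity_proportion)
  sim <- simulate_camera_data(truth, scores, "Jun", "adult",
                              deployment_s = dep, seed = 8,
                              stay_measured = 10)
  n <- sim$counts$n_passages
  expect_equal(mean(n), mu_target, tolerance = 0.02)
  expect_equal(var(n), mu_target + mu_target^2 / 2, tolerance = 0.1)
  # timestamps live inside the month and stays are positive
  expect_true(all(format(sim$detections$timestamp, "%m") == "06"))
  expect_true(all(sim$detections$staying_time_s > 0, na.rm = TRUE))
  expect_equal(sum(!is.na(sim$detections$staying_time_s)), 10)
})

test_that("zero expected density yields no detections", {
  truth <- simulate_truth(months = "Jun", juvenile_months = character(0))
  scores <- tibble::tibble(id = "c1", PC1 = 0, PC2 = 0, PC3 = 0, PC4 = 0)
  sim <- simulate_camera_data(truth, scores, "Jun", "adult",
                              deployment_s = 0, seed = 1)
  expect_equal(sim$counts$n_passages, 0L)
  expect_equal(nrow(sim$detections), 0L)
})

test_that("simulated harvest is Poisson around catchability x traps x density", {
  truth <- simulate_truth(months = "Jan", juvenile_months = character(0))
  ud <- tibble::tibble(unit_id = sprintf("u%04d", 1:5000), month = "Jan",
                       density = 10)
  traps <- tidyr::expand_grid(unit_id = ud$unit_id, month = "Jan",
                              trap_type = c("box", "snare"))
  traps$n_traps <- 25L
  h <- simulate_harvest(truth, ud, seed = 4, trap_table = traps)
  lam_box <- 0.02 * 25 * 10
  expect_equal(mean(h$n_trapped[h$trap_type == "box"]), lam_box,
               tolerance = 0.02)
  # doubling catchability doubles the mean catch
  truth2 <- simulate_truth(months = "Jan", juvenile_months = character(0),
                           c_box = 0.04)
  h2 <- simulate_harvest(truth2, ud, seed = 4, trap_table = traps)
  expect_equal(mean(h2$n_trapped[h2$trap_type == "box"]) /
                 mean(h$n_trapped[h$trap_type == "box"]), 2, tolerance = 0.05)
  # zero traps force zero catch
  traps$n_traps <- 0L
  h0 <- simulate_harvest(truth, ud, seed = 4, trap_table = traps)
  expect_true(all(h0$n_trapped == 0))
})

test_that("a complete simulated study passes every validator on re-read", {
  st <- fixture_study()
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_no_warning({
    det <- read_detections(file.path(dir, "detections.csv"))
    read_deployments(file.path(dir, "deployments.csv"))
    read_landscape(file.path(dir, "landscape_sites.csv"))
    read_landscape(file.path(dir, "landscape_cells.csv"))
    read_harvest(file.path(dir, "harvest.csv"))
    read_units(file.path(dir, "units.csv"))
  })
  expect_identical(simulate_study("small", seed = 2)$counts, st$counts)
})
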