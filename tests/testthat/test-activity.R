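vm_pdf_hours <- function(h, mu_h, kappa) {
  # closed-form von Mises pdf on the 24 h clock, per hour
  th <- (h %% 24) / 24 * 2 * pi
  mu <- (mu_h %% 24) / 24 * 2 * pi
  exp(kappa * cos(th - mu)) / (2 * pi * besselI(kappa, 0)) * 2 * pi / 24
}

rvm_hours <- function(n, mu_h, kappa) {
  # inverse-free sampler via rejection against a uniform envelope
  out <- numeric(0)
  fmax <- vm_pdf_hours(mu_h, mu_h, kappa)
  while (length(out) < n) {
    x <- runif(2 * n, 0, 24)
    keep <- runif(2 * n) < vm_pdf_hours(x, mu_h, kappa) / fmax
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}

trapz_circle <- function(dens) sum(dens$density_per_h) * (24 / length(dens$grid_h))

test_that("fitted circular densities integrate to one", {
  set.seed(1)
  for (times in list(runif(50, 0, 24), rvm_hours(200, 3, 2))) {
    d <- fit_circular_density(times)
    expect_equal(trapz_circle(d), 1, tolerance = 1e-6)
  }
})

test_that("identical timestamps give a sharply peaked density that still integrates to one", {
  d <- fit_circular_density(rep(13.5, 25))
  expect_equal(trapz_circle(d), 1, tolerance = 1e-6)
  expect_gt(max(d$density_per_h), 10 * (1 / 24))
  expect_lt(activity_proportion(d), 0.15)
})

test_that("kernel estimate approaches the true von Mises density", {
  set.seed(42)
  times <- rvm_hours(4000, 22, 2)
  d <- fit_circular_density(times)
  truth <- vm_pdf_hours(d$grid_h, 22, 2)
  expect_lt(max(abs(d$density_per_h - truth)), 0.05)
})

test_that("activity proportion is the uniform-to-peak density ratio", {
  grid <- seq(0, 24, length.out = 513)[-513]
  # exactly uniform density
  expect_identical(activity_proportion(circular_density(grid, rep(1 / 24, 512))), 1)
  # two-level step: active half the day at double the uniform level
  step <- ifelse(grid >= 6 & grid < 18, 2 / 24, 0)
  expect_equal(activity_proportion(circular_density(grid, step)), 0.5)
})

test_that("activity proportion matches the closed-form von Mises peak ratio", {
  set.seed(7)
  kappa <- 1
  times <- rvm_hours(3000, 2, kappa)
  d <- fit_circular_density(times)
  truth <- (1 / (2 * pi)) / (exp(kappa) / (2 * pi * besselI(kappa, 0)))
  expect_equal(activity_proportion(d), truth, tolerance = 0.08)
})

test_that("evenly spread detections give an activity level of one", {
  d <- fit_circular_density(seq(0, 24, length.out = 49)[-49])
  expect_equal(activity_proportion(d), 1, tolerance = 1e-6)
})

test_that("activity proportion is invariant under clock rotation", {
  set.seed(5)
  times <- rvm_hours(500, 4, 1.5)
  p0 <- activity_proportion(fit_circular_density(times))
  for (shift in c(3.21, 11.5, 17)) {
    p <- activity_proportion(fit_circular_density((times + shift) %% 24))
    expect_equal(p, p0, tolerance = 1e-3)
  }
})

test_that("concentrating detections into a narrower window lowers the proportion", {
  base <- qunif(seq(0.01, 0.99, length.out = 60))   # deterministic spread
  widths <- c(16, 8, 4, 2)
  props <- vapply(widths, function(w) {
    activity_proportion(fit_circular_density(12 + (base - 0.5) * w))
  }, numeric(1))
  expect_true(all(diff(props) < 0))
})

test_that("active time is deployment times proportion, with guarded inputs", {
  expect_identical(active_time(86400, 0.5), 43200)
  expect_identical(active_time(0, 0.7), 0)
  expect_error(active_time(-1, 0.5), "must be")
  expect_error(active_time(100, 1.4), "<= 1")
  expect_error(active_time(100, 0))
})

test_that("too few detections instructs pooling", {
  expect_error(fit_circular_density(c(1, 2, 3)), "pool")
})

test_that("monthly estimation pools adjacent months when sparse", {
  st <- fixture_study()
  act <- estimate_activity(st$detections, st$config)
  expect_true(all(act$proportion > 0 & act$proportion <= 1, na.rm = TRUE))
  # the simulated rhythm is shared across months; estimates agree roughly
  adult <- act$proportion[act$age_class == "adult"]
  expect_lt(diff(range(adult)), 0.25)
})

test_that("a simulated activity schedule yields the right active time at scale", {
  # enough cameras that the circadian sample is in the estimator's
  # large-sample regime
  truth <- simulate_truth(months = "Jun", juvenile_months = character(0))
  scores <- tibble::tibble(id = sprintf("c%04d", 1:2500),
                           PC1 = 0, PC2 = 0, PC3 = 0, PC4 = 0)
  sim <- simulate_camera_data(truth, scores, "Jun", "adult", seed = 14,
                              stay_measured = 0)
  lt <- as.POSIXlt(sim$detections$timestamp)
  tod <- lt$hour + lt$min / 60 + lt$sec / 3600
  expect_gt(length(tod), 2000)
  p <- activity_proportion(fit_circular_density(tod))
  expect_equal(p, truth$activity_proportion, tolerance = 0.05)
  dep_s <- 30 * 86400
  expect_equal(active_time(dep_s, p), dep_s * truth$activity_proportion,
               tolerance = 0.05)
})
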