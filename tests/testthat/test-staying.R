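quadrature_mean <- function(pdf) {
  integrate(function(t) t * pdf(t), 0, Inf, rel.tol = 1e-10)$value
}

test_that("analytic family means match numerical integration", {
  fam <- boarest:::stay_family
  cases <- list(
    list("exponential", c(log_rate = log(0.2)),
         function(t) dexp(t, 0.2)),
    list("exponential", c(log_rate = log(3)),
         function(t) dexp(t, 3)),
    list("gamma", c(log_shape = log(2), log_rate = log(1 / 3)),
         function(t) dgamma(t, shape = 2, rate = 1 / 3)),
    list("gamma", c(log_shape = log(0.7), log_rate = log(2)),
         function(t) dgamma(t, shape = 0.7, rate = 2)),
    list("lognormal", c(meanlog = 1, log_sdlog = log(0.8)),
         function(t) dlnorm(t, 1, 0.8)),
    list("weibull", c(log_shape = log(1.5), log_scale = log(4)),
         function(t) dweibull(t, 1.5, 4)),
    list("weibull", c(log_shape = log(0.9), log_scale = log(10)),
         function(t) dweibull(t, 0.9, 10)))
  for (cs in cases) {
    analytic <- fam(cs[[1]])$mean(cs[[2]])
    expect_equal(analytic, quadrature_mean(cs[[3]]), tolerance = 1e-6,
                 label = cs[[1]])
  }
  # the gamma(shape 2, scale 3) textbook case
  expect_equal(fam("gamma")$mean(c(log(2), log(1 / 3))), 6)
  expect_equal(fam("lognormal")$mean(c(0, log(1e-10))), 1, tolerance = 1e-6)
  expect_equal(fam("exponential")$mean(c(log(1 / 5))), 5)
})

test_that("an exponential fit recovers the true mean staying time", {
  set.seed(10)
  times <- rexp(2000, rate = 0.2)
  fit <- fit_staying_time(times, "exponential", seed = 3)
  expect_equal(fit$expected_staying_time_s, 5, tolerance = 0.05)
  expect_equal(expected_staying_time(fit), mean(times), tolerance = 0.05)
})

test_that("near-degenerate lognormal data pin the mean at the common value", {
  set.seed(2)
  times <- rlnorm(300, meanlog = log(7), sdlog = 0.005)
  fit <- fit_staying_time(times, "lognormal", seed = 4)
  expect_equal(fit$expected_staying_time_s, 7, tolerance = 0.01)
})

test_that("WAIC selection is an argmin with a parsimony tie-break", {
  mk <- function(family, waic, npar) {
    structure(list(family = family, random_effect = FALSE, waic = waic,
                   npar = npar, data_fingerprint = c(10, 55, 12)),
              class = "boarest_staying")
  }
  picked <- select_best(list(mk("exponential", 100, 1), mk("gamma", 90, 2),
                             mk("weibull", 95, 2)))
  expect_equal(picked$waic, 90)
  picked <- select_best(list(mk("gamma", 88, 2), mk("exponential", 88, 1)))
  expect_equal(picked$family, "exponential")
  bad <- mk("gamma", 90, 2); bad$data_fingerprint <- c(11, 50, 9)
  expect_error(select_best(list(mk("exponential", 100, 1), bad)),
               "same data")
})

test_that("the WAIC sweep identifies lognormal staying times", {
  set.seed(77)
  wins <- 0L
  reps <- 5L
  for (r in seq_len(reps)) {
    times <- rlnorm(300, meanlog = 1, sdlog = 0.8)
    sw <- staying_time_sweep(times, iterations = 2500, burn_in = 800,
                             thin = 5, seed = 100 + r)
    expect_equal(nrow(sw$comparison), 4L)
    if (sw$best$family == "lognormal") wins <- wins + 1L
    # the misspecified memoryless family must fit clearly worse
    w <- sw$comparison
    expect_gt(w$waic[w$family == "exponential"],
              w$waic[w$family == "lognormal"])
  }
  expect_gte(wins, 4L)
})

test_that("camera random effects are estimable and WAIC-comparable", {
  set.seed(31)
  cams <- rep(sprintf("c%02d", 1:10), each = 40)
  b <- rnorm(10, 0, 0.5)[rep(1:10, each = 40)]
  times <- rlnorm(400, meanlog = 1 + b, sdlog = 0.4)
  plain <- fit_staying_time(times, "lognormal", seed = 8)
  re <- fit_staying_time(times, "lognormal", camera_ids = cams,
                         random_effect = TRUE, seed = 8,
                         iterations = 6000, burn_in = 2000, thin = 5)
  expect_lt(re$waic, plain$waic)
  expect_equal(select_best(list(plain, re))$random_effect, TRUE)
})

test_that("invalid staying-time inputs are rejected", {
  expect_error(fit_staying_time(c(1, -2, 3), "gamma"), "positive")
  expect_error(fit_staying_time(rexp(20) + 1, "cauchy"), "Unknown")
  expect_error(fit_staying_time(rexp(20) + 1, "lognormal",
                                random_effect = TRUE), "camera_ids")
})
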