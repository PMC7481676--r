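test_that("loadings are orthonormal and variances match a brute-force eigendecomposition", {
  comp <- random_compositions(50, seed = 7)
  basis <- fit_pca(comp)
  L <- basis$loadings
  expect_lt(max(abs(crossprod(L) - diag(6))), 1e-10)

  # independent oracle: eigenvalues of the correlation matrix
  x <- as.matrix(comp[-1])
  ev <- eigen(cor(x), symmetric = TRUE)$values
  expect_equal(basis$explained, ev / sum(ev), tolerance = 1e-10)

  # deterministic sign convention
  dominant <- vapply(seq_len(6), function(j) L[which.max(abs(L[, j])), j],
                     numeric(1))
  expect_true(all(dominant > 0))
})

test_that("a dominant correlated class pair loads on the first axis", {
  set.seed(3)
  n <- 400
  base <- rnorm(n)
  x <- cbind(broadleaf = 40 + 8 * base + rnorm(n, 0, 0.5),
             conifer = 40 - 8 * base + rnorm(n, 0, 0.5),
             farmland = 5 + rnorm(n), bamboo = 3 + rnorm(n, 0, 0.5),
             abandoned = 3 + rnorm(n, 0, 0.5),
             residential = 2 + rnorm(n, 0, 0.3))
  comp <- dplyr::bind_cols(tibble::tibble(id = as.character(seq_len(n))),
                           tibble::as_tibble(x))
  basis <- fit_pca(comp)
  # the forest gradient is the only structure: PC1 explains ~2/6 of the
  # correlation-scale variance and is carried by the correlated pair
  expect_equal(basis$explained[1], 2 / 6, tolerance = 0.05)
  l1 <- abs(basis$loadings[, 1])
  expect_true(all(l1[c("broadleaf", "conifer")] > 0.6))
  expect_true(all(l1[3:6] < 0.2))
})

test_that("too few sites or a constant class are handled", {
  comp <- random_compositions(6)
  expect_error(fit_pca(comp), "more camera sites")
  comp <- random_compositions(30)
  comp$residential <- 1
  expect_warning(b <- fit_pca(comp, n_axes = 4), "constant")
  expect_equal(length(b$classes), 5L)
})

test_that("projection is the standardized matrix product, centered at the site mean", {
  comp <- random_compositions(40, seed = 9)
  basis <- fit_pca(comp)

  mean_comp <- tibble::tibble(id = "mean",
                              !!!as.list(setNames(basis$center, basis$classes)))
  s0 <- project_pca(basis, mean_comp)
  expect_equal(unlist(s0[paste0("PC", 1:4)]), setNames(rep(0, 4), paste0("PC", 1:4)),
               tolerance = 1e-12)

  # sites projected through their own basis reproduce the fit scores
  again <- project_pca(basis, comp)
  expect_equal(as.matrix(again[-1]), as.matrix(basis$site_scores[-1]),
               tolerance = 1e-10)

  # matrix-product oracle on an arbitrary cell
  cell <- random_compositions(1, seed = 99)
  sc <- project_pca(basis, cell)
  z <- (unlist(cell[-1]) - basis$center) / basis$scale
  oracle <- as.vector(z %*% basis$loadings[, 1:4])
  expect_equal(unname(unlist(sc[-1])), oracle, tolerance = 1e-10)
})

test_that("all six axes reconstruct the standardized data", {
  comp <- random_compositions(35, seed = 5)
  basis <- fit_pca(comp, n_axes = 6)
  x <- as.matrix(comp[-1])
  z <- scale(x, center = basis$center, scale = basis$scale)
  scores <- z %*% basis$loadings
  expect_lt(max(abs(scores %*% t(basis$loadings) - z)), 1e-8)
})

test_that("fitted site scores have zero mean and eigenvalue variances", {
  comp <- random_compositions(60, seed = 13)
  basis <- fit_pca(comp)
  s <- as.matrix(basis$site_scores[-1])
  expect_lt(max(abs(colMeans(s))), 1e-12)
  ev <- eigen(cor(as.matrix(comp[-1])), symmetric = TRUE)$values
  expect_equal(unname(apply(s, 2, var)), ev[1:4] * (59 / 59), tolerance = 1e-8)
})

test_that("missing class columns are rejected at projection", {
  comp <- random_compositions(20)
  basis <- fit_pca(comp)
  expect_error(project_pca(basis, comp[-2]), "missing required column")
})
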