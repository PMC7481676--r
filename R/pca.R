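#' Summarise landscape compositions into principal components
#'
#' Standardises the six land-use percentages across camera sites
#' (mean 0, s.d. 1) and computes a principal-component basis from their
#' correlation structure. The first `n_axes` scores are the habitat
#' covariates of the density model. Axis signs follow a deterministic
#' convention: the largest-magnitude loading of each axis is positive.
#'
#' @param compositions Data frame with an `id` column and the six class
#'   percentage columns (see [read_landscape()]); one row per camera site.
#' @param n_axes Number of axes retained as covariates (default 4).
#' @return A `boarest_pca` object: per-class `center` and `scale` taken from
#'   the camera sites, the full 6x6 orthonormal `loadings` matrix,
#'   `explained` variance fractions, `n_axes`, and `site_scores` (tibble of
#'   retained scores for the fitted sites).
#' @export
#' @examples
#' sim <- simulate_landscape(n_sites = 40, n_cells = 50, n_units = 4, seed = 1)
#' basis <- fit_pca(sim$sites)
#' basis$explained
fit_pca <- function(compositions, n_axes = 4) {
  assert_columns(compositions, c("id", LANDSCAPE_CLASSES), "site compositions")
  x <- as.matrix(compositions[LANDSCAPE_CLASSES])
  if (nrow(x) <= ncol(x)) {
    stop_boarest("PCA needs more camera sites than landscape classes.")
  }
  sds <- apply(x, 2L, sd)
  keep <- sds > 0
  if (!all(keep)) {
    warn(sprintf("Dropping constant landscape class(es): %s",
                 paste(colnames(x)[!keep], collapse = ", ")))
    x <- x[, keep, drop = FALSE]
  }
  if (n_axes > ncol(x)) {
    stop_boarest("n_axes exceeds the number of varying landscape classes.")
  }
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  load <- p$rotation
  # sign convention: dominant loading of each axis is positive
  flip <- apply(load, 2L, function(v) sign(v[which.max(abs(v))]))
  load <- sweep(load, 2L, flip, `*`)
  explained <- p$sdev^2 / sum(p$sdev^2)
  scores <- scale(x, center = p$center, scale = p$scale) %*% load[, seq_len(n_axes), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(n_axes))
  basis <- structure(list(classes = colnames(x),
                          center = p$center, scale = p$scale,
                          loadings = load, explained = explained,
                          n_axes = as.integer(n_axes)),
                     class = "boarest_pca")
  basis$site_scores <- dplyr::bind_cols(tibble::tibble(id = compositions$id),
                                        tibble::as_tibble(scores))
  basis
}

#' Project compositions onto a fitted landscape basis
#'
#' Grid cells (or new sites) are standardised with the *camera-site* means
#' and standard deviations stored in the basis, so the resulting scores live
#' on the same scale as the covariates the habitat coefficients were
#' estimated on.
#'
#' @param basis A `boarest_pca` from [fit_pca()].
#' @param compositions Data frame with `id` and the six class columns.
#' @return Tibble of `id` and `PC1..PCn` scores.
#' @export
project_pca <- function(basis, compositions) {
  stopifnot(inherits(basis, "boarest_pca"))
  assert_columns(compositions, c("id", basis$classes), "compositions")
  x <- as.matrix(compositions[basis$classes])
  z <- scale(x, center = basis$center, scale = basis$scale)
  s <- z %*% basis$loadings[, seq_len(basis$n_axes), drop = FALSE]
  colnames(s) <- paste0("PC", seq_len(basis$n_axes))
  dplyr::bind_cols(tibble::tibble(id = compositions$id),
                   tibble::as_tibble(s))
}

#' @export
print.boarest_pca <- function(x, ...) {
  cat("<boarest_pca> landscape principal components\n")
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  axes kept: %d | explained: %s\n", x$n_axes,
              paste(sprintf("%.0f%%", 100 * x$explained[seq_len(x$n_axes)]),
                    collapse = ", ")))
  invisible(x)
}

#' @export
tidy.boarest_pca <- function(x, ...) {
  tibble::tibble(
    axis = rep(paste0("PC", seq_along(x$explained)), each = length(x$classes)),
    class = rep(x$classes, times = length(x$explained)),
    loading = as.vector(x$loadings),
    explained = rep(x$explained, each = length(x$classes)))
}

#' Plot landscape-axis loadings
#' @param object A `boarest_pca`.
#' @param ... Unused.
#' @return A ggplot of factor loadings per retained axis.
#' @export
autoplot.boarest_pca <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$axis %in% paste0("PC", seq_len(object$n_axes)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$loading)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~axis) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "loading")
}
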