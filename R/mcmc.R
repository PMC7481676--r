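# Adaptive Metropolis-within-Gibbs machinery shared by the staying-time
# fits and the joint model, plus the split-chain Rhat diagnostic.
#
# Each scalar coordinate gets a Gaussian random-walk proposal whose log
# step size is adapted in batches during burn-in toward an acceptance rate
# of 0.44 (the scalar optimum), with adaptation amounts shrinking as
# 1/sqrt(batch) so the chain is asymptotically valid.

amwg_chain <- function(lp, init, n_iter, burn_in, thin,
                       lower = NULL, upper = NULL, track = NULL,
                       batch = 50L) {
  d <- length(init)
  lower <- lower %||% rep(-Inf, d)
  upper <- upper %||% rep(Inf, d)
  theta <- init
  cur_lp <- lp(theta)
  if (!is.finite(cur_lp)) {
    stop_boarest("Log posterior is not finite at the initial value.")
  }
  ls <- rep(0, d)          # log proposal s.d. per coordinate
  acc <- rep(0L, d)
  kept_idx <- seq.int(burn_in + thin, n_iter, by = thin)
  draws <- matrix(NA_real_, length(kept_idx), d)
  colnames(draws) <- names(init)
  tracked <- if (!is.null(track)) {
    matrix(NA_real_, length(kept_idx), length(track(theta)))
  }
  k <- 1L
  for (it in seq_len(n_iter)) {
    for (j in seq_len(d)) {
      prop <- theta
      prop[j] <- theta[j] + exp(ls[j]) * rnorm(1L)
      if (prop[j] < lower[j] || prop[j] > upper[j]) next
      prop_lp <- lp(prop)
      if (is.finite(prop_lp) && log(runif(1L)) < prop_lp - cur_lp) {
        theta <- prop
        cur_lp <- prop_lp
        acc[j] <- acc[j] + 1L
      }
    }
    if (it <= burn_in && it %% batch == 0L) {
      delta <- min(0.1, 1 / sqrt(it / batch))
      ls <- ls + ifelse(acc / batch > 0.44, delta, -delta)
      acc[] <- 0L
    }
    if (k <= length(kept_idx) && it == kept_idx[k]) {
      draws[k, ] <- theta
      if (!is.null(tracked)) tracked[k, ] <- track(theta)
      k <- k + 1L
    }
  }
  list(draws = draws, tracked = tracked, step = exp(ls))
}

run_amwg <- function(lp, init_fn, n_iter, burn_in, thin, chains, seed,
                     lower = NULL, upper = NULL, track = NULL) {
  out <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + 1000L * (ch - 1L))
    out[[ch]] <- amwg_chain(lp, init_fn(ch), n_iter, burn_in, thin,
                            lower = lower, upper = upper, track = track)
  }
  out
}

#' Split-chain potential scale reduction factor (Rhat)
#'
#' Gelman-Rubin diagnostic with each chain split in half, so within-chain
#' trends also inflate the statistic. Values below 1.1 are taken as MCMC
#' convergence.
#'
#' @param draws Matrix of posterior draws, iterations x chains, for one
#'   parameter (at least 2 chains and 10 draws each).
#' @return The Rhat value (>= 1 up to numerical tolerance).
#' @export
#' @examples
#' set.seed(1)
#' rhat(matrix(rnorm(2000), 1000, 2))
rhat <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) stop_boarest("Rhat needs at least 2 chains.")
  if (nrow(draws) < 10L) stop_boarest("Rhat needs at least 10 draws per chain.")
  n2 <- floor(nrow(draws) / 2L)
  halves <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j) {
    cbind(draws[seq_len(n2), j], draws[n2 + seq_len(n2), j])
  }))
  m <- ncol(halves)
  n <- nrow(halves)
  w <- mean(apply(halves, 2L, var))
  b <- n * var(colMeans(halves))
  if (w == 0) return(1)   # all chains constant and equal
  sqrt(((n - 1) / n * w + b / n) / w)
}
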