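# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture_study <- function() {
  if (is.null(.fixtures$study)) {
    .fixtures$study <- simulate_study("small", seed = 2)
  }
  .fixtures$study
}

fixture_data <- function() {
  if (is.null(.fixtures$data)) {
    .fixtures$data <- suppressMessages(prepare_joint_data(fixture_study()))
  }
  .fixtures$data
}

random_compositions <- function(n, seed = 1) {
  set.seed(seed)
  raw <- matrix(rgamma(n * 6, shape = c(6, 4, 3, 1, 1.5, 1)), n, 6,
                byrow = TRUE)
  pct <- raw / rowSums(raw) * runif(n, 90, 99)
  colnames(pct) <- c("broadleaf", "conifer", "farmland", "bamboo",
                     "abandoned", "residential")
  dplyr::bind_cols(tibble::tibble(id = sprintf("s%03d", seq_len(n))),
                   tibble::as_tibble(pct))
}
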