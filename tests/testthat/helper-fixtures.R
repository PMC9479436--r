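# Shared fixtures and independent oracles for the test suite.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# A quiet, fully deterministic cohort config: no noise, no change.
zero_noise_config <- function(n = 2L, days = 2L, seed = 1L,
                              perturbations = matrix(0.25, 4, 4)) {
  cohort_config(
    n_per_stratum = n, days_per_wave = days,
    between_sd = rep(0, 3), within_sd = rep(0, 3), slope_sd = rep(0, 3),
    change_perturbations = perturbations, seed = seed
  )
}

moderate_noise <- list(between_sd = rep(0.3, 3),
                       within_sd = c(0.3, 0.3, 0.15),
                       slope_sd = c(0.2, 0.2, 0.1))

# Independent balance-coordinate oracle: build the full orthonormal ilr
# basis matrix from the sign rows and multiply into log(x). This is a
# different construction from the grouped-geometric-mean implementation.
oracle_ilr <- function(x, signs) {
  V <- matrix(0, nrow(signs), ncol(signs))
  for (k in seq_len(nrow(signs))) {
    r <- sum(signs[k, ] > 0); s <- sum(signs[k, ] < 0)
    V[k, signs[k, ] > 0] <- sqrt(s / (r * (r + s)))
    V[k, signs[k, ] < 0] <- -sqrt(r / (s * (r + s)))
  }
  drop(V %*% log(x))
}

random_compositions <- function(n, D = 4L, seed = 1L) {
  set.seed(seed)
  m <- matrix(exp(rnorm(n * D, 0, 1.5)), n, D)
  colnames(m) <- behavior_parts()[seq_len(D)]
  m / rowSums(m)
}

# One simulated day composition (minutes, sums to 1440) with sleep
# bounded so it always fits an 8.5-h logged window.
random_day_target <- function(seed) {
  set.seed(seed)
  sleep <- runif(1, 330, 505)
  mvpa <- runif(1, 5, 90)
  lpa <- runif(1, 120, 330)
  sed <- 1440 - sleep - mvpa - lpa
  round(c(sleep = sleep, sed = sed, lpa = lpa, mvpa = mvpa))
}
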