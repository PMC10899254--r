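# Independent oracles and shared fixtures for the test suite.

# Direct evaluation of the DerSimonian-Laird formulas, written out
# step by step and kept independent of pool_random_effects().
dl_oracle <- function(yi, vi, level = 0.95) {
  k <- length(yi)
  w <- 1 / vi
  mu_fixed <- sum(w * yi) / sum(w)
  Q <- sum(w * (yi - mu_fixed)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w_star <- 1 / (vi + tau2)
  mu <- sum(w_star * yi) / sum(w_star)
  se <- sqrt(1 / sum(w_star))
  z <- qnorm(1 - (1 - level) / 2)
  list(mu = mu, se = se, ci_low = mu - z * se, ci_high = mu + z * se,
       tau2 = tau2, Q = Q,
       I2 = if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0,
       p = 2 * pnorm(-abs(mu / se)))
}

# A symmetric funnel: pairs of studies at +/- spread * si around `center`.
# Deterministic given the si grid; no randomness involved.
symmetric_funnel <- function(center = 0.2, spread = 1.2,
                             si_grid = seq(0.05, 0.30, length.out = 10)) {
  data.frame(yi = center + rep(spread * si_grid, each = 2) * c(1, -1),
             si = rep(si_grid, each = 2))
}

# Shared cache so expensive bootstrap runs are computed once per test run.
.sft_cache <- new.env(parent = emptyenv())

sft_world <- function() {
  if (is.null(.sft_cache$world)) {
    .sft_cache$cfg <- world_sim_config(seed = 11)
    .sft_cache$world <- generate_world(.sft_cache$cfg)
  }
  .sft_cache$world
}

sft_main_run <- function() {
  if (is.null(.sft_cache$main)) {
    w <- sft_world()
    .sft_cache$main <- bootstrap_sft(w$observations, w$grid, m = 500,
                                     reps = 200, seed = 3, num_trees = 200)
  }
  .sft_cache$main
}

# A small world for cheap structural tests of the bootstrap machinery.
small_world <- function(seed = 5) {
  generate_world(world_sim_config(n_cells = 150, n_obs = 120, seed = seed))
}
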