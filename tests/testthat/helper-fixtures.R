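# Shared fixtures, built in code at test time.

# Small sensor montage keeps glmnet fits cheap in unit tests.
small_config <- function(...) {
  synth_config(n_sensors = 32L, ...)
}

# Decoded-probability null trials: sigmoid-squashed AR(1) channels, one per
# state. Matches what decoding pure AR(1) sensor noise through fixed linear
# models produces (each decoded column is a monotone transform of an AR(1)
# mixture), without the cost of simulating sensors.
null_prob_trials <- function(n_trials, n_bins, ar = 0.8) {
  lapply(seq_len(n_trials), function(i)
    stats::plogis(ar1_noise(n_bins, 6L, ar, sqrt(1 - ar^2))))
}

# Probability matrix with explicit planted chains: background p0 with state
# `chain[m]` raised to p1 at onset + (m-1) * lag_bins, repeated at each onset.
planted_X <- function(n_bins, chain, onsets, lag_bins = 4L, p0 = 0.05,
                      p1 = 0.95, n_states = 6L) {
  X <- matrix(p0, n_bins, n_states)
  for (o in onsets) {
    for (m in seq_along(chain)) {
      t <- o + (m - 1L) * lag_bins
      if (t <= n_bins) X[t, chain[m]] <- p1
    }
  }
  X
}

# A directed path of `len` states walked along graph edges.
graph_path <- function(graph, len, start = 1L) {
  s <- start
  out <- s
  for (m in seq_len(len - 1L)) {
    s <- graph$succ[s, "up"]
    out <- c(out, s)
  }
  out
}

# Random row-stochastic matrix (generic transition structure for oracles).
random_stochastic <- function(K = 6L) {
  m <- matrix(stats::runif(K * K), K, K)
  m / rowSums(m)
}
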