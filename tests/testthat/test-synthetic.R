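test_that("state patterns are unit norm, weakly correlated, reproducible", {
  set.seed(31)
  p <- make_state_patterns(6, 134)
  expect_equal(sqrt(rowSums(p^2)), rep(1, 6), tolerance = 1e-12)
  r <- cor(t(p))
  expect_lt(max(abs(r[upper.tri(r)])), 0.3)
  set.seed(31)
  expect_identical(p, make_state_patterns(6, 134))
})

test_that("AR(1) noise matches its stationary theory", {
  set.seed(32)
  x <- ar1_noise(10000, 3, 0.8, 1)
  ac <- apply(x, 2, function(v) cor(v[-1], v[-length(v)]))
  expect_true(all(abs(ac - 0.8) < 0.05))
  expect_equal(mean(apply(x, 2, var)), 1 / (1 - 0.8^2), tolerance = 0.1)
  set.seed(33)
  w <- ar1_noise(10000, 3, 0, 1)
  acw <- apply(w, 2, function(v) cor(v[-1], v[-length(v)]))
  expect_true(all(abs(acw) < 0.05))
})

test_that("localizer epochs carry the evoked pattern at the peak latency", {
  set.seed(34)
  cfg <- small_config()
  pat <- make_state_patterns(6, cfg$n_sensors)
  loc <- simulate_localizer(cfg, pat, n_trials_per_state = 6)
  expect_equal(unname(table(loc$labels)), rep(6L, 6), ignore_attr = TRUE)
  t200 <- which.min(abs(loc$times_ms - 200))
  t0 <- which.min(abs(loc$times_ms - 0))
  proj <- function(ti) {
    mean(vapply(seq_along(loc$labels), function(i)
      sum(loc$epochs[i, ti, ] * pat[loc$labels[i], ]), numeric(1)))
  }
  expect_gt(proj(t200), proj(t0) + 1)
  # zero snr: no evoked content at the peak
  set.seed(34)
  cfg0 <- small_config(snr = 0)
  loc0 <- simulate_localizer(cfg0, pat, n_trials_per_state = 6)
  proj0 <- mean(vapply(seq_along(loc0$labels), function(i)
    sum(loc0$epochs[i, t200, ] * pat[loc0$labels[i], ]), numeric(1)))
  expect_lt(abs(proj0), 0.5)
})

test_that("planning simulation logs chains that follow graph edges", {
  g <- task_graph()
  set.seed(35)
  cfg <- small_config()
  pat <- make_state_patterns(6, cfg$n_sensors)
  pl <- simulate_planning(cfg, pat, g, 30)
  expect_gt(nrow(pl$events), 10)
  for (r in seq_len(nrow(pl$events))) {
    chain <- as.integer(strsplit(pl$events$chain[r], "-")[[1]])
    expect_equal(length(chain), pl$events$length[r])
    for (m in seq_len(length(chain) - 1)) {
      if (pl$events$direction[r] == "reverse") {
        # temporal successor must be a graph predecessor
        expect_equal(g$T[chain[m + 1], chain[m]], 0.5)
      } else {
        expect_equal(g$T[chain[m], chain[m + 1]], 0.5)
      }
    }
  }
  # a 4-state chain at 40 ms spans 120 ms = 12 bins of activation onsets
  four <- pl$events[pl$events$length == 4, ]
  if (nrow(four) > 0) {
    expect_equal(unique(four$lag_ms), 40)
    expect_equal(chain_duration_ms(4, unique(four$lag_ms)), 120)
  }
})

test_that("event_rate 0 gives an empty log and pure noise", {
  g <- task_graph()
  set.seed(36)
  cfg <- small_config(event_rate = 0)
  pat <- make_state_patterns(6, cfg$n_sensors)
  pl <- simulate_planning(cfg, pat, g, 20)
  expect_equal(nrow(pl$events), 0L)
  expect_equal(nrow(pl$ts$markers), 0L)
  # marginal variance consistent with unit-SD AR noise
  expect_equal(mean(apply(pl$ts$data, 2, var)), 1, tolerance = 0.15)
})

test_that("generators are deterministic under a fixed seed", {
  g <- task_graph()
  cfg <- small_config()
  set.seed(37); pat1 <- make_state_patterns(6, cfg$n_sensors)
  set.seed(37); pat2 <- make_state_patterns(6, cfg$n_sensors)
  expect_identical(pat1, pat2)
  set.seed(38); a <- simulate_planning(cfg, pat1, g, 10)
  set.seed(38); b <- simulate_planning(cfg, pat1, g, 10)
  expect_identical(a$ts$data, b$ts$data)
  expect_identical(a$events, b$events)
})

test_that("synth_config validates its invariants", {
  expect_error(synth_config(ar_coeff = 1), "ar_coeff")
  expect_error(synth_config(lag_ms = 45), "multiple")
  expect_error(synth_config(direction_mix = 2), "probability")
  cfg <- synth_config(length_dist = c(`2` = 2, `3` = 2))
  expect_equal(sum(cfg$length_dist), 1)
})
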