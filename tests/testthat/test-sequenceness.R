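test_that("transition_transform follows the matrix algebra", {
  g <- task_graph()
  set.seed(51)
  X <- matrix(runif(60), 10, 6)
  expect_equal(transition_transform(X, diag(6)), X)
  # one-hot S1 projects 0.5 onto its successors S2 and S5
  X1 <- matrix(0, 5, 6); X1[3, 1] <- 1
  XF <- transition_transform(X1, g$T)
  expect_equal(XF[3, ], c(0, 0.5, 0, 0, 0.5, 0), ignore_attr = TRUE)
  expect_equal(transition_transform(X, g$T, steps = 2),
               transition_transform(X, g$T) %*% g$T)
})

test_that("curve, compiled paths and loop oracle agree", {
  g <- task_graph()
  set.seed(52)
  for (i in 1:10) {
    X <- matrix(runif(6 * 120), 120, 6)
    Tm <- if (i %% 2) g$T else random_stochastic()
    cv <- sequenceness_curve(X, Tm, lags_ms = c(10, 40, 90))
    bf <- vapply(c(10, 40, 90), function(l)
      brute_force_sequenceness(X, Tm, l), numeric(1))
    expect_equal(cv$diff, bf, tolerance = 1e-10)
    fast <- sequenceness:::.diff_curve_fast(X, Tm, c(1L, 4L, 9L))
    expect_equal(fast, cv$diff, tolerance = 1e-12)
    fr <- sequenceness:::.mean_curve_fast(list(X), Tm, c(10, 40, 90),
                                          c(1L, 4L, 9L))
    expect_equal(fr$forward, cv$forward, tolerance = 1e-12)
    expect_equal(fr$reverse, cv$reverse, tolerance = 1e-12)
  }
})

test_that("oracle and curve are zero on constant input", {
  g <- task_graph()
  X <- matrix(0.25, 80, 6)
  expect_equal(brute_force_sequenceness(X, g$T, 40), 0)
  expect_equal(sequenceness_curve(X, g$T, lags_ms = 40)$diff, 0)
})

test_that("sign convention: planted forward pairs give positive forward", {
  g <- task_graph()
  X <- planted_X(400, chain = c(1, 2), onsets = seq(10, 350, by = 25))
  cv <- sequenceness_curve(X, g$T, lags_ms = seq(10, 100, 10))
  expect_equal(cv$lag_ms[which.max(cv$forward)], 40)
  expect_gt(cv$diff[cv$lag_ms == 40], 0)
  # reverse planted pairs (edge S1->S2 played S2 then S1) flip the sign
  Xr <- planted_X(400, chain = c(2, 1), onsets = seq(10, 350, by = 25))
  cvr <- sequenceness_curve(Xr, g$T, lags_ms = seq(10, 100, 10))
  expect_lt(cvr$diff[cvr$lag_ms == 40], 0)
  expect_equal(cvr$lag_ms[which.max(abs(cvr$diff))], 40)
})

test_that("transpose antisymmetry and relabeling equivariance hold", {
  g <- task_graph()
  set.seed(53)
  for (i in 1:8) {
    X <- matrix(runif(6 * 150), 150, 6)
    cv <- sequenceness_curve(X, g$T, lags_ms = seq(10, 80, 10))
    cvt <- sequenceness_curve(X, t(g$T), lags_ms = seq(10, 80, 10))
    expect_equal(cvt$diff, -cv$diff, tolerance = 1e-12)
    sig <- sample(6)
    # relabeled world: columns X[, sig] under matrix T[sig, sig]
    cvp <- sequenceness_curve(X[, sig], g$T[sig, sig],
                              lags_ms = seq(10, 80, 10))
    expect_equal(cvp$diff, cv$diff, tolerance = 1e-12)
    expect_equal(cvp$forward, cv$forward, tolerance = 1e-12)
  }
})

test_that("label-class enumeration matches the graph's symmetry structure", {
  g <- task_graph()
  cls <- enumerate_label_classes(g$T)
  expect_equal(cls$n_classes, 30L)
  expect_true(all(cls$class_size == 24L))
  expect_equal(sum(cls$class_size), factorial(6))
  expect_false(is.na(cls$identity_rep))
  expect_false(is.na(cls$reversal_rep))
  expect_equal(length(shuffle_representatives(g$T)), 28L)
  # distinct permuted matrices across representatives
  mats <- lapply(cls$reps, function(p) g$T[p, p])
  keys <- vapply(mats, function(m) paste(m, collapse = ","), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  set.seed(54)
  R <- matrix(runif(36), 6, 6)
  expect_equal(enumerate_label_classes(R)$n_classes, 720L)
  U <- matrix(1 / 5, 6, 6); diag(U) <- 0
  expect_equal(enumerate_label_classes(U)$n_classes, 1L)
})

test_that("permutation thresholds: global dominates per-lag; planted signal detected", {
  g <- task_graph()
  set.seed(55)
  X_null <- null_prob_trials(6, 400)
  null <- permutation_thresholds(X_null, g$T)
  expect_equal(null$n_shuffles, 28L)
  expect_true(all(null$global_threshold >= null$per_lag_threshold))
  expect_equal(null$nominal_p, 1 / 28)
  # planted reverse chains, a different random directed path per trial
  # (a single repeated path can be matched by a relabeled graph and is
  # correctly not distinguishable from its shuffle null)
  X_sig <- lapply(1:12, function(i) {
    path <- sequenceness:::.random_path(g, 4L)
    planted_X(600, chain = rev(path), onsets = seq(10, 560, by = 30)) +
      matrix(runif(3600, 0, 0.02), 600)
  })
  nsig <- permutation_thresholds(X_sig, g$T)
  expect_true(nsig$significant)
  expect_lt(nsig$observed$diff[nsig$observed$lag_ms == 40], 0)
  expect_equal(nsig$p_value, 1 / 29)
})

test_that("sample-order null agrees with direct recomputation", {
  g <- task_graph()
  set.seed(56)
  X <- matrix(runif(1200), 200, 6)
  p <- sample.int(200)
  fast <- sequenceness:::.cpp_sample_null(X, g$T, as.integer(c(2L, 5L)),
                                          matrix(p, 200))
  ref <- sequenceness_curve(X[p, ], g$T, lags_ms = c(20, 50))
  expect_equal(as.numeric(fast), ref$diff, tolerance = 1e-12)
})

test_that("length-n curves localize planted reverse 4-chains", {
  g <- task_graph()
  set.seed(57)
  chain4 <- rev(graph_path(g, 4))
  X <- planted_X(800, chain = chain4, onsets = seq(10, 680, by = 40)) +
    matrix(runif(4800, 0, 0.02), 800)
  for (n in 3:4) {
    cv <- length_n_curve(X, g$T, n, lags_ms = seq(10, 100, 10))
    expect_equal(cv$lag_ms[which.max(cv$reverse)], 40)
    expect_lt(cv$diff[cv$lag_ms == 40], 0)
  }
  # relabeling equivariance of the length-n measure
  sig <- sample(6)
  cv3 <- length_n_curve(X, g$T, 3, lags_ms = c(40, 80))
  cv3p <- length_n_curve(X[, sig], g$T[sig, sig], 3, lags_ms = c(40, 80))
  expect_equal(cv3$diff, cv3p$diff, tolerance = 1e-10)
})

test_that("isolated pairs do not masquerade as length-3 chains", {
  g <- task_graph()
  set.seed(58)
  # plant only 2-chains (reverse pairs), well separated
  pair <- rev(graph_path(g, 2))
  X <- planted_X(900, chain = pair, onsets = seq(10, 800, by = 45)) +
    matrix(runif(5400, 0, 0.02), 900)
  obs <- length_n_curve(X, g$T, 3, lags_ms = 40)$diff
  # state-identity null band for the length-3 statistic
  reps <- shuffle_representatives(g$T)
  null_vals <- vapply(reps, function(p)
    length_n_curve(X, g$T[p, p], 3, lags_ms = 40)$diff, numeric(1))
  expect_lt(abs(obs), max(abs(null_vals)))
})

test_that("pairwise sequenceness is antisymmetric and localizes the pair", {
  g <- task_graph()
  set.seed(59)
  X <- matrix(runif(6000), 1000, 6)
  s12 <- pairwise_sequenceness(X, 1, 2, 40)
  s21 <- pairwise_sequenceness(X, 2, 1, 40)
  expect_equal(s12, -s21, tolerance = 1e-12)
  # planted S2-then-S1 (reverse of edge S1->S2)
  Xp <- planted_X(1000, chain = c(2, 1), onsets = seq(10, 950, by = 30)) +
    matrix(runif(6000, 0, 0.02), 1000)
  M <- pairwise_sequenceness_matrix(Xp, 40)
  expect_equal(max(abs(M)), abs(M[1, 2]))
  expect_equal(M, -t(M), tolerance = 1e-12)
  # iid noise: all pair scores inside a loose null band
  Mn <- pairwise_sequenceness_matrix(X, 40)
  expect_lt(max(abs(Mn)), 0.2)
})

test_that("timing helpers encode the compression arithmetic", {
  expect_equal(chain_duration_ms(4, 40), 120)
  expect_equal(round(temporal_compression(350, 40)), 9)
  expect_equal(round(shuffle_nominal_level(28), 3), 0.036)
})
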