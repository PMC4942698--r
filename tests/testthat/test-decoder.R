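test_that("balanced partitions satisfy the three constraints", {
  set.seed(61)
  # equal counts: one left out per class
  lab <- rep(1:6, each = 16)
  p <- balanced_partition(lab)
  expect_equal(unname(table(lab[p$train])), rep(15L, 6), ignore_attr = TRUE)
  expect_equal(unname(table(lab[p$test])), rep(1L, 6), ignore_attr = TRUE)
  expect_setequal(c(p$train, p$test), seq_along(lab))
  # unequal counts: left-in tied to the smallest class minus one
  lab2 <- rep(1:6, times = c(17, 16, 16, 16, 16, 16))
  p2 <- balanced_partition(lab2)
  expect_equal(unname(table(lab2[p2$train])), rep(15L, 6),
               ignore_attr = TRUE)
  expect_equal(sort(unname(table(lab2[p2$test]))), c(1L, 1L, 1L, 1L, 1L, 2L),
               ignore_attr = TRUE)
  expect_error(balanced_partition(c(1, 1, 2)), "at least 2")
})

test_that("trained classifiers have the documented shape and penalty limits", {
  set.seed(62)
  cfg <- synth_config()   # full 134-sensor montage for the length check
  pat <- make_state_patterns(6, cfg$n_sensors)
  loc <- simulate_localizer(cfg, pat, n_trials_per_state = 4)
  clf <- suppressWarnings(train_state_classifiers(loc, lambda = 0.006))
  expect_equal(nrow(clf$beta), 135L)   # 134 slopes + intercept
  expect_equal(ncol(clf$beta), 6L)
  expect_true(all(is.finite(clf$beta)))
  # large penalty: all slopes exactly zero, prediction = base rate
  clf_big <- suppressWarnings(train_state_classifiers(loc, lambda = 10))
  expect_true(all(clf_big$beta[-1, ] == 0))
  X <- predict_state_probabilities(clf_big, matrix(0, 5, 134))
  expect_equal(unname(X[1, ]), rep(mean(loc$labels == 1), 6),
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("slope sparsity is non-increasing in the penalty", {
  set.seed(63)
  cfg <- small_config()
  pat <- make_state_patterns(6, cfg$n_sensors)
  loc <- simulate_localizer(cfg, pat, n_trials_per_state = 8)
  nnz <- vapply(c(0.001, 0.006, 0.03, 0.15), function(lam) {
    clf <- suppressWarnings(train_state_classifiers(loc, lambda = lam))
    sum(clf$beta[-1, ] != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("prediction is a per-state sigmoid and permutation-equivariant", {
  clf <- structure(list(beta = matrix(0, 4, 3), lambda = 0.01,
                        train_latency_ms = 200, n_sensors = 3L,
                        states = 1:3),
                   class = "state_classifiers")
  X <- predict_state_probabilities(clf, matrix(rnorm(15), 5, 3))
  expect_true(all(X == 0.5))
  # single unit slope: sigmoid arithmetic
  clf$beta[2, 1] <- 1
  Xs <- predict_state_probabilities(clf, matrix(c(0, log(3), 0), 1, 3))
  expect_equal(Xs[1, 1], 0.5)
  Xs2 <- predict_state_probabilities(clf, matrix(c(log(3), 0, 0), 1, 3))
  expect_equal(Xs2[1, 1], 0.75)
  # permuting sensors consistently in data and weights leaves X unchanged
  set.seed(64)
  beta <- matrix(rnorm(4 * 3), 4, 3)
  data <- matrix(rnorm(30), 10, 3)
  perm <- c(3, 1, 2)
  clf_a <- structure(list(beta = beta, lambda = 0, train_latency_ms = 200,
                          n_sensors = 3L, states = 1:3),
                     class = "state_classifiers")
  clf_b <- clf_a
  clf_b$beta <- rbind(beta[1, , drop = FALSE],
                      beta[-1, , drop = FALSE][perm, ])
  expect_equal(predict_state_probabilities(clf_b, data[, perm]),
               predict_state_probabilities(clf_a, data),
               tolerance = 1e-12)
  # rows need not sum to one
  X6 <- predict_state_probabilities(clf_a, data)
  expect_false(isTRUE(all.equal(rowSums(X6), rep(1, 10))))
})

test_that("cross-validation report finds the evoked peak and its threshold", {
  set.seed(65)
  cfg <- small_config(snr = 5)
  pat <- make_state_patterns(6, cfg$n_sensors)
  loc <- simulate_localizer(cfg, pat, n_trials_per_state = 8)
  rep_ <- suppressWarnings(crossval_report(
    loc, lambda = 0.01, n_partitions = 3, n_shuffles = 20))
  expect_true(all(rep_$accuracy >= 0 & rep_$accuracy <= 1))
  # accuracy peaks within the top of the evoked kernel (adjacent bins carry
  # 98% of the peak amplitude, so single-bin jitter is expected)
  expect_lte(abs(rep_$peak_time_ms - 200), 10)
  expect_gt(rep_$accuracy[rep_$times_ms == 200], 0.5)
  expect_gt(rep_$max_accuracy, 0.5)
  expect_true(rep_$significant)
  suppressWarnings(expect_warning(
    crossval_report(loc, lambda = 0.01, n_partitions = 1, n_shuffles = 5),
    "shuffles"))
})

test_that("label-shuffle threshold is calibrated on pure-noise localizers", {
  set.seed(66)
  cfg <- small_config(snr = 0)
  exceed <- 0
  n_runs <- 30
  for (r in seq_len(n_runs)) {
    pat <- make_state_patterns(6, cfg$n_sensors)
    loc <- simulate_localizer(cfg, pat, n_trials_per_state = 4,
                              window_ms = c(0, 250))
    rep_ <- suppressWarnings(crossval_report(
      loc, lambda = 0.01, n_partitions = 2, n_shuffles = 20))
    exceed <- exceed + rep_$significant
  }
  # nominal 5%; binomial(30, 0.05) upper 99.9% bound
  expect_lte(exceed, 7)
})

test_that("penalty selection picks dominant penalties per held-out subject", {
  # crafted score table: lambda 2 dominates for everyone
  curves <- array(0, c(4, 3, 5))
  curves[, 2, 3] <- c(0.5, 0.6, 0.4, 0.55)
  sel <- select_penalty(curves, lambdas = c(0.001, 0.006, 0.03))
  expect_equal(unname(sel$lambda), rep(0.006, 4))
  expect_equal(sum(sel$histogram), 4)
  expect_equal(unname(sel$histogram["0.006"]), 4)
  # leave-one-out: a subject's own curve does not drive its selection
  curves2 <- array(0, c(3, 2, 4))
  curves2[1, 1, 1] <- 100            # subject 1 idiosyncratically loves l1
  curves2[c(2, 3), 2, 2] <- 1        # everyone else supports l2
  sel2 <- select_penalty(curves2, lambdas = c(1, 2))
  expect_equal(unname(sel2$lambda[1]), 2)
  expect_error(select_penalty(array(0, c(1, 2, 3)), c(1, 2)), "two subjects")
})

test_that("penalty curves feed selection end to end on planted data", {
  set.seed(67)
  g <- task_graph()
  cfg <- small_config()
  subjects <- lapply(1:2, function(s) {
    pat <- make_state_patterns(6, cfg$n_sensors)
    loc <- simulate_localizer(cfg, pat, n_trials_per_state = 8)
    planning <- lapply(1:2, function(t) simulate_planning(cfg, pat, g, 12)$ts)
    list(localizer = loc, planning = planning)
  })
  lambdas <- c(0.006, 5)   # 5 forces all-zero slopes: no signal possible
  curves <- suppressWarnings(
    penalty_curve_table(subjects, lambdas, g, lags_ms = seq(20, 60, 20)))
  sel <- select_penalty(curves, lambdas)
  expect_equal(unname(sel$lambda), rep(0.006, 2))
})
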