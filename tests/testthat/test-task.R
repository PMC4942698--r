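test_that("default graph satisfies the documented structural constraints", {
  g <- task_graph()
  expect_setequal(unname(g$succ["S1", ]), c(2L, 5L))        # S1 -> {S2, S5}
  expect_equal(unname(g$succ["S4", "up"]), 5L)              # S4 -> S5
  expect_equal(unname(g$succ["S5", "up"]), 6L)              # S5 -> S6
  expect_equal(rowSums(g$T), rep(1, 6), tolerance = 1e-12,
               ignore_attr = TRUE)
  for (s in 1:6) {
    nz <- g$T[s, g$T[s, ] > 0]
    expect_equal(unname(nz), c(0.5, 0.5))
    expect_equal(g$T[s, s], 0)
  }
})

test_that("graph construction rejects malformed edge specs", {
  expect_error(task_graph(cbind(up = c(1, 3, 4, 5, 6, 1),
                                down = c(5, 6, 1, 2, 3, 4))), "self-loop")
  expect_error(task_graph(cbind(up = rep(2L, 6), down = rep(2L, 6))),
               "must differ")
  expect_error(task_graph(cbind(up = c(2, 3, 4, 5, 6, 7),
                                down = c(5, 6, 1, 2, 3, 4))), "out of range")
})

test_that("enumerate_plans is complete, ordered and sized 2^depth", {
  p4 <- enumerate_plans(4)
  expect_equal(nrow(p4), 16L)
  expect_equal(nrow(unique(as.data.frame(p4))), 16L)
  expect_equal(unname(p4[1, ]), rep("up", 4))
  expect_equal(unname(p4[16, ]), rep("down", 4))
  expect_equal(nrow(enumerate_plans(1)), 2L)
  p3 <- enumerate_plans(3)
  expect_equal(dim(p3), c(8L, 3L))
})

test_that("evaluate_plan applies reward collection and the neg sign flip", {
  g <- task_graph()
  # walking S1 -> S2 -> S3 accumulates -4 then -9; S3 is neg so -9 -> +9
  tr <- trial_spec(1, c(3, 6), c(0, -4, -5, 0, 0, 0))
  out <- evaluate_plan(g, tr, c("up", "up", "up", "up"))
  expect_equal(out$path, c(2L, 3L, 4L, 5L))
  expect_equal(out$totals[1:2], c(-4L, 9L))
  # all rewards zero, no neg on path: every plan earns 0
  tr0 <- trial_spec(2, c(1, 4), rep(0, 6))
  expect_true(all(plan_values(g, tr0) == 0))
  # hand-stepped example: rewards S1..S6 = 0..5, start S1, all-up path
  tr2 <- trial_spec(1, c(1, 6), c(0, 1, 2, 3, 4, 5))
  out2 <- evaluate_plan(g, tr2, rep("up", 4))
  expect_equal(out2$path, c(2L, 3L, 4L, 5L))
  expect_equal(out2$earnings, 10)
  expect_error(evaluate_plan(g, tr2, c("up", "sideways", "up", "up")),
               "invalid action")
})

test_that("sign-flip property: a neg final state negates the pre-flip total", {
  g <- task_graph()
  set.seed(42)
  checked <- 0
  for (i in 1:60) {
    rewards <- sample(-5:5, 6, replace = TRUE)
    start <- sample(6, 1)
    plan <- sample(c("up", "down"), 4, replace = TRUE)
    path <- evaluate_plan(g, trial_spec(start, c(1, 2), rewards), plan)$path
    last <- path[4]
    off_path <- setdiff(1:6, c(path, start))
    if (any(path[1:3] == last) || length(off_path) < 1) next
    out <- evaluate_plan(g, trial_spec(start, c(last, off_path[1]), rewards),
                         plan)
    # pre-flip total v = total after 3 moves plus the final state's reward
    v <- out$totals[3] + rewards[last]
    expect_equal(out$totals[4], -v)
    checked <- checked + 1
  }
  expect_gte(checked, 20)
})

test_that("drift_rewards is uniform over -1/0/+1 and respects bounds", {
  set.seed(7)
  draws <- replicate(10000, drift_rewards(0L))
  freqs <- table(factor(draws, levels = -1:1)) / 10000
  expect_true(all(abs(freqs - 1 / 3) < 0.02))
  expect_true(all(replicate(500, drift_rewards(5L)) <= 5))
  expect_true(all(replicate(500, drift_rewards(-5L)) >= -5))
  r <- sample(-5:5, 6, replace = TRUE)
  for (i in 1:1000) r <- drift_rewards(r)
  expect_true(all(r >= -5 & r <= 5) && all(r == round(r)))
})

test_that("generate_session is seed-deterministic with valid trials", {
  g <- task_graph()
  set.seed(11); s1 <- generate_session(g, 25)
  set.seed(11); s2 <- generate_session(g, 25)
  expect_identical(s1, s2)
  expect_true(all(s1$neg1 != s1$neg2))
  rl <- as.matrix(s1[paste0("r", 1:6)])
  expect_true(all(rl >= -5 & rl <= 5))
  # consecutive rewards differ by at most 1
  expect_true(all(abs(diff(rl)) <= 1))
})

test_that("adversarial filter enforces the optimal-minus-greedy margin", {
  g <- task_graph()
  set.seed(12)
  sess <- generate_session(g, 10, adversarial_filter = TRUE, margin = 2)
  for (t in sess$trial) {
    tr <- session_trial(sess, t)
    gap <- max(plan_values(g, tr)) - sequenceness:::.greedy_earnings(g, tr)
    expect_gte(gap, 2)
  }
})
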