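test_that("mixed intercept collapses to the grand mean when sigma_b is 0", {
  set.seed(71)
  subj <- rep(1:10, each = 20)
  y <- 0.3 + rnorm(200, 0, 0.5)      # no subject effect
  fit <- mixed_intercept_fit(y, subj)
  expect_equal(fit$beta, mean(y), tolerance = 1e-6)
  expect_gte(fit$sigma_b, 0)
  expect_gt(fit$p, 0); expect_lte(fit$p, 1)
})

test_that("one observation per subject matches the one-sample t-test", {
  set.seed(72)
  y <- rnorm(100, 0.01, 0.05)
  expect_warning(fit <- mixed_intercept_fit(y, 1:100), "confounded")
  tt <- t.test(y)
  expect_equal(fit$p, tt$p.value, tolerance = 1e-12)
  expect_equal(fit$beta, mean(y))
})

test_that("mixed model log-likelihood dominates the sigma_b = 0 submodel", {
  set.seed(73)
  subj <- rep(1:12, each = 15)
  y <- 0.1 + rnorm(12, 0, 0.3)[subj] + rnorm(180, 0, 0.2)
  fit <- mixed_intercept_fit(y, subj)
  # OLS intercept-only model is the sigma_b = 0 submodel (ML variant)
  n <- length(y)
  s2 <- mean((y - mean(y))^2)
  ll0 <- -0.5 * n * (log(2 * pi * s2) + 1)
  expect_gte(fit$log_lik, ll0 - 1e-6)
})

test_that("covariate extension recovers a fixed slope", {
  set.seed(74)
  subj <- rep(1:15, each = 20)
  x <- rnorm(300)
  y <- 0.05 + 0.4 * x + rnorm(15, 0, 0.1)[subj] + rnorm(300, 0, 0.2)
  fit <- mixed_intercept_fit(y, subj, x = x)
  expect_lt(abs(fit$slope - 0.4), 3 * fit$slope_se)
  expect_lt(fit$slope_p, 1e-6)
})

test_that("subject-mean regression handles exact and null fits", {
  x <- seq(0.1, 1.2, length.out = 12)
  fit <- suppressWarnings(subject_mean_regression(x, 2 * x))
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_lt(fit$p, 1e-6)
  set.seed(75)
  # slope recovery within its confidence interval
  x2 <- rnorm(30); y2 <- 1 + 0.5 * x2 + rnorm(30, 0, 0.3)
  f2 <- subject_mean_regression(x2, y2)
  expect_lt(abs(f2$slope - 0.5), 3 * f2$se)
  expect_error(subject_mean_regression(rep(1, 5), rnorm(5)), "variance")
})

test_that("pair ANOVA has the (11, 132) structure and a textbook oracle", {
  set.seed(76)
  scores <- expand.grid(pair = paste0("e", 1:12), session = 1:12)
  scores$value <- rnorm(144)
  out <- pair_anova(scores)
  expect_equal(c(out$df1, out$df2), c(11, 132))
  # textbook one-way F from sums of squares
  gm <- mean(scores$value)
  means <- tapply(scores$value, scores$pair, mean)
  ssb <- sum(12 * (means - gm)^2)
  ssw <- sum((scores$value - means[scores$pair])^2)
  f_ref <- (ssb / 11) / (ssw / 132)
  expect_equal(out$F, f_ref, tolerance = 1e-8)
  # identical groups: zero between-group variance
  same <- expand.grid(pair = paste0("e", 1:3), session = 1:4)
  same$value <- rep(c(1, 2, 3, 4), each = 3)
  expect_lt(pair_anova(same)$F, 1e-20)
})

test_that("tuple contrast counts chosen/unchosen edges and detects planting", {
  g <- task_graph()
  set.seed(77)
  n_sub <- 6; n_tr <- 12
  edges <- task_edges(g)
  choices <- do.call(rbind, lapply(1:n_sub, function(s) {
    sess <- generate_session(g, n_tr)
    ch <- simulate_choices("Plan", list(beta = 0.5), g, sess)
    data.frame(subject = s, trial = ch$trial, start = sess$start,
               ch[paste0("move", 1:4)])
  }))
  make_scores <- function(boost) {
    do.call(rbind, lapply(seq_len(nrow(choices)), function(r) {
      ch <- choices[r, ]
      s <- ch$start
      chosen <- matrix(0L, 4, 2)
      for (m in 1:4) {
        s2 <- g$succ[s, ch[[paste0("move", m)]]]
        chosen[m, ] <- c(s, s2)
        s <- s2
      }
      sc <- rnorm(nrow(edges), 0, 0.05)
      if (boost > 0) {
        hit <- paste(edges[, 1], edges[, 2]) %in%
          paste(chosen[, 1], chosen[, 2])
        sc[hit] <- sc[hit] + boost
      }
      data.frame(subject = ch$subject, trial = ch$trial,
                 from = edges[, 1], to = edges[, 2], score = sc)
    }))
  }
  tc <- tuple_contrast(make_scores(0.3), choices, g)
  expect_true(all(tc$trials$n_chosen <= 4 & tc$trials$n_chosen >= 1))
  expect_lt(tc$fit$p, 0.01)
  expect_gt(tc$fit$beta, 0)
  tc1 <- tuple_contrast(make_scores(0.3), choices, g, mode = "first_move")
  expect_true(all(tc1$trials$n_chosen == 1))
  expect_true(all(tc1$trials$n_unchosen == 11))
  # no planted preference: contrast near zero
  tc0 <- tuple_contrast(make_scores(0), choices, g)
  expect_lt(abs(tc0$fit$beta), 3 * tc0$fit$se + 0.05)
})
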