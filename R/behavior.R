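#' Behavioral choice models
#'
#' Four models of how an agent picks its four-move plan on each trial:
#'
#' * **Plan** - full-depth tree search. The agent evaluates all 16 possible
#'   four-move plans with [plan_values()] and chooses with a softmax over plan
#'   earnings (inverse temperature `beta`). This is the structurally optimal
#'   strategy.
#' * **Greedy** - knows the task structure but chooses each move by a softmax
#'   over the local one-step return of the two actions (reward of the entered
#'   state, with the neg sign-flip applied to the running total).
#' * **Qfirst** - structure-free. Keeps a Q-table over the 12 state-action
#'   pairs; only the (start state, first move) pair is updated after each
#'   trial, with learning rate `alpha` toward the realized trial earnings.
#'   The first move is a softmax over `Q[start, ]`; later moves are uniform
#'   (without structure knowledge the agent cannot track its state during
#'   feedback-free pre-entry).
#' * **Qall** - like Qfirst but uses the structure to track the current state:
#'   every move is a softmax over `Q[state, ]` and all four visited
#'   state-action pairs are updated toward the realized earnings.
#'
#' All models are expressed as a probability distribution over the 16 plans
#' (the per-move softmax chains factorize exactly into this distribution).
#'
#' @name behavior_models
NULL

BEHAVIOR_MODELS <- c("Plan", "Qfirst", "Qall", "Greedy")

#' Initialize a Q-table
#'
#' @param graph A [task_graph()].
#' @return Zero matrix, one row per state and one column per action
#'   (6 x 2 = 12 entries for the default maze).
#' @export
init_q_table <- function(graph) {
  matrix(0, graph$n_states, length(graph$actions),
         dimnames = list(graph$state_names, graph$actions))
}

# Plan index (row of enumerate_plans) of a character action vector.
.plan_index <- function(plan, depth = length(plan)) {
  bits <- as.integer(plan == "down")
  sum(bits * 2L^((depth - 1):0)) + 1L
}

# Per-step greedy values: for state s and running total v, the one-step
# outcome of each action (reward added, then neg flip of the total).
.one_step_values <- function(graph, trial, s, total) {
  vapply(graph$actions, function(a) {
    s2 <- graph$succ[s, a]
    v <- total + trial$rewards[s2]
    if (s2 %in% trial$neg) v <- -v
    v
  }, numeric(1))
}

#' Choice probabilities of a behavioral model on one trial
#'
#' @param model One of `"Plan"`, `"Qfirst"`, `"Qall"`, `"Greedy"`.
#' @param params Named list or vector; `beta` (inverse temperature, >= 0) for
#'   all models, plus `alpha` (learning rate) for Qfirst/Qall (alpha only
#'   affects updates, not the within-trial probabilities).
#' @param graph A [task_graph()].
#' @param trial A [trial_spec()].
#' @param q Current Q-table (required for Qfirst/Qall).
#' @param depth Plan length (default 4).
#' @return Probability vector over the `2^depth` plans, ordered as
#'   [enumerate_plans()]; entries are non-negative and sum to 1.
#' @export
choice_model_probs <- function(model, params, graph, trial, q = NULL,
                               depth = 4L) {
  model <- match.arg(model, BEHAVIOR_MODELS)
  beta <- params[["beta"]]
  .assert(is.finite(beta) || is.infinite(beta), "beta must be numeric")
  .assert(!is.na(beta) && beta >= 0, "beta must be >= 0")
  plans <- enumerate_plans(depth)
  n_plans <- nrow(plans)

  if (model == "Plan") {
    return(.softmax(plan_values(graph, trial, depth), beta))
  }

  if (model == "Qfirst") {
    .assert(!is.null(q), "Qfirst needs a Q-table")
    p_first <- .softmax(q[trial$start, ], beta)
    p <- p_first[match(plans[, 1], graph$actions)] * (0.5^(depth - 1))
    return(as.numeric(p))
  }

  # Greedy and Qall walk each plan, chaining per-move softmax probabilities.
  p <- numeric(n_plans)
  for (i in seq_len(n_plans)) {
    s <- trial$start
    total <- 0
    pr <- 1
    for (m in seq_len(depth)) {
      vals <- if (model == "Greedy") .one_step_values(graph, trial, s, total)
              else q[s, ]
      step_p <- .softmax(vals, beta)
      a <- plans[i, m]
      pr <- pr * step_p[[a]]
      s <- graph$succ[s, a]
      total <- total + trial$rewards[s]
      if (s %in% trial$neg) total <- -total
    }
    p[i] <- pr
  }
  p
}

# Post-trial Q update toward the realized trial earnings.
.q_update <- function(model, q, graph, trial, plan, earnings, alpha) {
  if (model == "Qfirst") {
    q[trial$start, plan[1]] <- q[trial$start, plan[1]] +
      alpha * (earnings - q[trial$start, plan[1]])
  } else if (model == "Qall") {
    s <- trial$start
    for (m in seq_along(plan)) {
      q[s, plan[m]] <- q[s, plan[m]] + alpha * (earnings - q[s, plan[m]])
      s <- graph$succ[s, plan[m]]
    }
  }
  q
}

#' Simulate an agent's choices over a session
#'
#' @inheritParams choice_model_probs
#' @param session A [generate_session()] data.frame.
#' @return Data.frame with columns `trial`, `move1..move4` (actions) and
#'   `earnings`.
#' @export
simulate_choices <- function(model, params, graph, session, depth = 4L) {
  model <- match.arg(model, BEHAVIOR_MODELS)
  plans <- enumerate_plans(depth)
  q <- init_q_table(graph)
  out <- vector("list", nrow(session))
  for (t in session$trial) {
    trial <- session_trial(session, t, graph$n_states)
    p <- choice_model_probs(model, params, graph, trial, q, depth)
    i <- sample.int(length(p), 1, prob = p)
    plan <- plans[i, ]
    earnings <- evaluate_plan(graph, trial, plan)$earnings
    if (model %in% c("Qfirst", "Qall")) {
      q <- .q_update(model, q, graph, trial, plan, earnings, params[["alpha"]])
    }
    out[[t]] <- data.frame(trial = t, t(plan), earnings = earnings)
  }
  do.call(rbind, out)
}

#' Log-likelihood of observed choices under a behavioral model
#'
#' Trials are processed in order; for Qfirst/Qall the Q-table is updated after
#' each trial using the realized earnings of the observed plan.
#'
#' @inheritParams choice_model_probs
#' @param choices Data.frame as returned by [simulate_choices()] (columns
#'   `trial`, `move1..move4`).
#' @param session The [generate_session()] the choices were made on.
#' @return Scalar log-likelihood (<= 0).
#' @export
choice_log_likelihood <- function(model, params, choices, graph, session,
                                  depth = 4L) {
  model <- match.arg(model, BEHAVIOR_MODELS)
  move_cols <- paste0("move", seq_len(depth))
  q <- init_q_table(graph)
  ll <- 0
  for (t in choices$trial) {
    trial <- session_trial(session, t, graph$n_states)
    plan <- as.character(choices[choices$trial == t, move_cols])
    p <- choice_model_probs(model, params, graph, trial, q, depth)
    pi <- p[.plan_index(plan, depth)]
    ll <- ll + log(max(pi, 1e-300))
    if (model %in% c("Qfirst", "Qall")) {
      earnings <- evaluate_plan(graph, trial, plan)$earnings
      q <- .q_update(model, q, graph, trial, plan, earnings, params[["alpha"]])
    }
  }
  ll
}

# Static per-dataset quantities reused across likelihood evaluations:
# plan earnings matrix, chosen plan indices, per-step one-step ("greedy")
# action values along the observed path, and per-trial realized earnings.
.precompute_behavior <- function(choices, graph, session, depth = 4L) {
  move_cols <- paste0("move", seq_len(depth))
  n <- nrow(choices)
  E <- matrix(0, n, 2L^depth)
  chosen <- integer(n)
  start <- integer(n)
  G <- numeric(n)
  gvals <- array(0, c(n, depth, 2L))
  act <- matrix(0L, n, depth)
  for (r in seq_len(n)) {
    t <- choices$trial[r]
    trial <- session_trial(session, t, graph$n_states)
    plan <- as.character(choices[r, move_cols])
    E[r, ] <- plan_values(graph, trial, depth)
    chosen[r] <- .plan_index(plan, depth)
    start[r] <- trial$start
    s <- trial$start
    total <- 0
    for (m in seq_len(depth)) {
      gvals[r, m, ] <- .one_step_values(graph, trial, s, total)
      act[r, m] <- match(plan[m], graph$actions)
      s <- graph$succ[s, plan[m]]
      total <- total + trial$rewards[s]
      if (s %in% trial$neg) total <- -total
    }
    G[r] <- total
  }
  list(E = E, chosen = chosen, start = start, G = G, gvals = gvals,
       act = act, n = n, depth = depth,
       succ = graph$succ, n_states = graph$n_states)
}

# Fast negative log-likelihoods on precomputed quantities. Each agrees with
# choice_log_likelihood() exactly (pinned by test).
.behavior_nll <- function(model, pre) {
  logsumexp2 <- function(a, b) {
    m <- pmax(a, b)
    m + log(exp(a - m) + exp(b - m))
  }
  switch(model,
    Plan = function(theta) {
      z <- exp(theta[1]) * pre$E
      zmax <- apply(z, 1, max)
      lse <- zmax + log(rowSums(exp(z - zmax)))
      -sum(z[cbind(seq_len(pre$n), pre$chosen)] - lse)
    },
    Greedy = function(theta) {
      beta <- exp(theta[1])
      v1 <- beta * pre$gvals[, , 1]
      v2 <- beta * pre$gvals[, , 2]
      vch <- ifelse(pre$act == 1L, v1, v2)
      -sum(vch - logsumexp2(v1, v2))
    },
    Qfirst = function(theta) {
      beta <- exp(theta[1]); alpha <- stats::plogis(theta[2])
      q <- matrix(0, pre$n_states, 2)
      ll <- 0
      for (r in seq_len(pre$n)) {
        s <- pre$start[r]; a <- pre$act[r, 1]
        z <- beta * q[s, ]
        ll <- ll + z[a] - max(z) - log(sum(exp(z - max(z))))
        q[s, a] <- q[s, a] + alpha * (pre$G[r] - q[s, a])
      }
      -(ll + pre$n * (pre$depth - 1) * log(0.5))
    },
    Qall = function(theta) {
      beta <- exp(theta[1]); alpha <- stats::plogis(theta[2])
      q <- matrix(0, pre$n_states, 2)
      ll <- 0
      for (r in seq_len(pre$n)) {
        s <- pre$start[r]
        path_s <- integer(pre$depth); path_a <- integer(pre$depth)
        for (m in seq_len(pre$depth)) {
          a <- pre$act[r, m]
          z <- beta * q[s, ]
          ll <- ll + z[a] - max(z) - log(sum(exp(z - max(z))))
          path_s[m] <- s; path_a[m] <- a
          s <- pre$succ[s, a]
        }
        for (m in seq_len(pre$depth)) {
          i <- path_s[m]; a <- path_a[m]
          q[i, a] <- q[i, a] + alpha * (pre$G[r] - q[i, a])
        }
      }
      -ll
    })
}

#' Maximum-likelihood fit of one behavioral model
#'
#' Parameters are optimized on transformed scales (`log beta`, `logit alpha`)
#' by a coarse grid search followed by Nelder-Mead (or Brent for the
#' one-parameter models) refinement. Likelihoods are evaluated on
#' precomputed per-trial quantities; the implementation is pinned against
#' [choice_log_likelihood()] by tests.
#'
#' @inheritParams choice_log_likelihood
#' @param model Model name.
#' @return List of class `behavior_fit`: `model`, `params`, `log_likelihood`,
#'   `n_params`, `n_trials` and `bic`.
#' @export
fit_choice_model <- function(model, choices, graph, session, depth = 4L) {
  model <- match.arg(model, BEHAVIOR_MODELS)
  has_alpha <- model %in% c("Qfirst", "Qall")
  pre <- .precompute_behavior(choices, graph, session, depth)
  nll <- .behavior_nll(model, pre)
  beta_grid <- log(c(0.03, 0.1, 0.3, 1, 3))
  if (has_alpha) {
    grid <- expand.grid(b = beta_grid, a = stats::qlogis(c(0.1, 0.3, 0.6)))
    vals <- apply(grid, 1, nll)
    start <- as.numeric(grid[which.min(vals), ])
    opt <- stats::optim(start, nll, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-8))
  } else {
    vals <- vapply(beta_grid, nll, numeric(1))
    start <- beta_grid[which.min(vals)]
    opt <- stats::optim(start, nll, method = "Brent",
                        lower = -8, upper = 5)
  }
  k <- if (has_alpha) 2L else 1L
  n <- nrow(choices)
  params <- list(beta = exp(opt$par[1]))
  if (has_alpha) params$alpha <- stats::plogis(opt$par[2])
  structure(list(model = model, params = params,
                 log_likelihood = -opt$value, n_params = k, n_trials = n,
                 bic = k * log(n) + 2 * opt$value),
            class = "behavior_fit")
}

#' Fit and rank all behavioral models
#'
#' Fits Plan, Qfirst, Qall and Greedy by maximum likelihood and ranks them by
#' BIC (computed with the number of trials as the sample size), alongside a
#' zero-parameter uniform-choice baseline. Degenerate choice data (a single
#' plan chosen on every trial) is flagged with a warning but still fitted.
#'
#' @inheritParams choice_log_likelihood
#' @return Data.frame of class `behavior_comparison`, one row per model,
#'   sorted by BIC (best first): `model`, `beta`, `alpha`, `log_likelihood`,
#'   `n_params`, `bic`.
#' @export
fit_and_compare <- function(choices, graph, session, depth = 4L) {
  .assert(nrow(choices) >= 1, "need at least one trial of choices")
  move_cols <- paste0("move", seq_len(depth))
  keys <- apply(choices[move_cols], 1, paste, collapse = "-")
  if (length(unique(keys)) == 1 && nrow(choices) > 1) {
    warning("degenerate choice data: the same plan was chosen on every trial")
  }
  fits <- lapply(BEHAVIOR_MODELS, fit_choice_model,
                 choices = choices, graph = graph, session = session,
                 depth = depth)
  n <- nrow(choices)
  rows <- lapply(fits, function(f) {
    data.frame(model = f$model, beta = f$params$beta,
               alpha = if (is.null(f$params$alpha)) NA_real_ else f$params$alpha,
               log_likelihood = f$log_likelihood, n_params = f$n_params,
               bic = f$bic)
  })
  rows[[length(rows) + 1L]] <- data.frame(
    model = "Uniform", beta = NA_real_, alpha = NA_real_,
    log_likelihood = n * log(1 / 2^depth), n_params = 0L,
    bic = -2 * n * log(1 / 2^depth))
  out <- do.call(rbind, rows)
  out <- out[order(out$bic), ]
  rownames(out) <- NULL
  class(out) <- c("behavior_comparison", "data.frame")
  out
}
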