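#' Six-state task graph
#'
#' Builds the deterministic two-action transition structure of the six-state
#' maze. From every state the two actions, `"up"` and `"down"`, each lead to a
#' different state, and no action maps a state to itself. The associated
#' transition matrix `T` places probability 0.5 on each of the two out-edges of
#' a state (equal probability over the two available actions).
#'
#' The true edge layout of the original maze is not published. The default used
#' here is the circulant layout `up: i -> i+1`, `down: i -> i+4` (mod 6,
#' 1-indexed), which satisfies all textual constraints on the maze (S1 leads to
#' S2 and S5 but not S3, S4 or S6; S4 -> S5 and S5 -> S6 are edges) and admits
#' a relabeling that maps `T` onto its transpose, so forward and reverse
#' trajectories are structurally symmetric. Any other layout can be supplied
#' via `edges`.
#'
#' @param edges Optional integer matrix with `n_states` rows and columns
#'   `up`, `down` giving the successor of each state under each action.
#'   `NULL` selects the default circulant layout.
#' @param n_states Number of states (default 6).
#' @param state_names Optional character labels, default `S1..Sn`.
#' @return An object of class `task_graph`: a list with elements `n_states`,
#'   `actions`, `succ` (state x action successor matrix), `T` (row-stochastic
#'   transition matrix) and `state_names`.
#' @examples
#' g <- task_graph()
#' g$succ["S1", ]          # successors of S1: S2 (up), S5 (down)
#' rowSums(g$T)            # all 1
#' @export
task_graph <- function(edges = NULL, n_states = 6L, state_names = NULL) {
  n_states <- as.integer(n_states)
  .assert(n_states >= 2, "n_states must be >= 2")
  actions <- c("up", "down")
  if (is.null(edges)) {
    up <- (seq_len(n_states)) %% n_states + 1L
    down <- (seq_len(n_states) + n_states - 3L) %% n_states + 1L
    edges <- cbind(up = up, down = down)
  } else {
    edges <- as.matrix(edges)
    .assert(nrow(edges) == n_states && ncol(edges) == 2,
            "edges must be an n_states x 2 matrix (up, down)")
    if (is.null(colnames(edges))) colnames(edges) <- actions
    edges <- edges[, actions, drop = FALSE]
    storage.mode(edges) <- "integer"
  }
  if (is.null(state_names)) state_names <- paste0("S", seq_len(n_states))
  .assert(length(state_names) == n_states, "need one name per state")

  for (s in seq_len(n_states)) {
    ss <- edges[s, ]
    .assert(all(ss >= 1L & ss <= n_states),
            "successor of state %d out of range", s)
    .assert(all(ss != s), "self-loop at state %d not allowed", s)
    .assert(ss[1] != ss[2],
            "up and down successors of state %d must differ", s)
  }

  Tm <- matrix(0, n_states, n_states,
               dimnames = list(state_names, state_names))
  for (s in seq_len(n_states)) Tm[s, edges[s, ]] <- 0.5
  rownames(edges) <- state_names
  structure(
    list(n_states = n_states, actions = actions, succ = edges, T = Tm,
         state_names = state_names),
    class = "task_graph"
  )
}

#' @export
print.task_graph <- function(x, ...) {
  cat(sprintf("<task_graph> %d states, actions up/down\n", x$n_states))
  for (s in seq_len(x$n_states)) {
    cat(sprintf("  %s -> up: %s, down: %s\n", x$state_names[s],
                x$state_names[x$succ[s, "up"]],
                x$state_names[x$succ[s, "down"]]))
  }
  invisible(x)
}

#' Directed edge list of a task graph
#'
#' @param graph A [task_graph()].
#' @return Integer matrix with columns `from`, `to`, one row per directed edge
#'   (12 rows for the six-state maze).
#' @export
task_edges <- function(graph) {
  stopifnot(inherits(graph, "task_graph"))
  cbind(from = rep(seq_len(graph$n_states), 2L),
        to = c(graph$succ[, "up"], graph$succ[, "down"]))
}

#' Trial specification
#'
#' A trial is defined by a start state, two distinct "neg" states (entering a
#' neg state multiplies the trial's running reward total by -1), and the
#' current reward (in pence, integer in `[-5, 5]`) attached to every state.
#'
#' @param start Start state id.
#' @param neg Integer vector of exactly two distinct neg-state ids.
#' @param rewards Integer rewards per state, each in `[-5, 5]`.
#' @param n_states Number of states the ids must respect.
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(start, neg, rewards, n_states = 6L) {
  start <- as.integer(start); neg <- as.integer(neg)
  .assert(length(start) == 1 && start >= 1 && start <= n_states,
          "start state out of range")
  .assert(length(neg) == 2 && neg[1] != neg[2] &&
            all(neg >= 1 & neg <= n_states),
          "neg must be two distinct state ids")
  .assert(length(rewards) == n_states, "need one reward per state")
  .assert(all(rewards == round(rewards)), "rewards must be integers")
  .assert(all(rewards >= -5 & rewards <= 5), "rewards must lie in [-5, 5]")
  structure(list(start = start, neg = neg,
                 rewards = as.integer(rewards)),
            class = "trial_spec")
}

#' Enumerate all action sequences of a given depth
#'
#' @param depth Number of sequential moves (default 4, giving the 16 possible
#'   four-move plans).
#' @return Character matrix, `2^depth` rows by `depth` columns, entries
#'   `"up"`/`"down"`, in deterministic lexicographic order with `"up"` ordered
#'   before `"down"` (row 1 is all-up).
#' @export
enumerate_plans <- function(depth = 4L) {
  depth <- as.integer(depth)
  .assert(depth >= 1, "depth must be >= 1")
  n <- 2L^depth
  out <- matrix("", n, depth)
  for (i in seq_len(n)) {
    bits <- as.integer(intToBits(i - 1L))[depth:1]
    out[i, ] <- c("up", "down")[bits + 1L]
  }
  colnames(out) <- paste0("move", seq_len(depth))
  out
}

#' Walk a plan through the maze and score it
#'
#' Implements the task's reward accounting: starting from `trial$start`, each
#' move enters the corresponding successor state; upon entering a state its
#' current reward is added to the running total, and then, if the state is a
#' neg state, the sign of the running total is flipped (e.g. a total of -9
#' becomes +9). The start state's own reward is not collected; only entered
#' states contribute.
#'
#' @param graph A [task_graph()].
#' @param trial A [trial_spec()].
#' @param plan Character (or 1/2 integer) vector of actions, usually length 4.
#' @return A list of class `plan_outcome` with `plan`, `path` (visited states,
#'   excluding the start), `totals` (running total after each entered state,
#'   post any sign flip) and `earnings` (final total, pence).
#' @export
evaluate_plan <- function(graph, trial, plan) {
  stopifnot(inherits(graph, "task_graph"), inherits(trial, "trial_spec"))
  if (is.numeric(plan)) plan <- graph$actions[plan]
  .assert(all(plan %in% graph$actions), "invalid action id in plan")
  s <- trial$start
  total <- 0L
  path <- integer(length(plan))
  totals <- integer(length(plan))
  for (m in seq_along(plan)) {
    s <- graph$succ[s, plan[m]]
    total <- total + trial$rewards[s]
    if (s %in% trial$neg) total <- -total
    path[m] <- s
    totals[m] <- total
  }
  structure(list(plan = plan, path = path, totals = totals,
                 earnings = total),
            class = "plan_outcome")
}

#' Earnings of every possible plan on a trial
#'
#' @inheritParams evaluate_plan
#' @param depth Plan length (default 4).
#' @return Numeric vector of length `2^depth`, ordered as [enumerate_plans()].
#' @export
plan_values <- function(graph, trial, depth = 4L) {
  plans <- enumerate_plans(depth)
  vapply(seq_len(nrow(plans)),
         function(i) evaluate_plan(graph, trial, plans[i, ])$earnings,
         numeric(1))
}

#' Random-walk drift of state rewards
#'
#' Each reward independently changes by -1, 0 or +1 pence with equal
#' probability, then is clamped to the permitted `[-5, 5]` range. Uses the
#' current RNG stream.
#'
#' @param rewards Integer rewards in `[-5, 5]`.
#' @return Drifted integer rewards, same length.
#' @export
drift_rewards <- function(rewards) {
  .assert(all(rewards >= -5 & rewards <= 5), "rewards must lie in [-5, 5]")
  step <- sample(c(-1L, 0L, 1L), length(rewards), replace = TRUE)
  pmin(pmax(as.integer(rewards) + step, -5L), 5L)
}

# Deterministic greedy walk: at each move pick the action whose one-step
# outcome (reward added, neg flip applied to the running total) is largest,
# breaking ties in favor of "up". Returns final earnings.
.greedy_earnings <- function(graph, trial, depth = 4L) {
  s <- trial$start
  total <- 0L
  for (m in seq_len(depth)) {
    vals <- vapply(graph$actions, function(a) {
      s2 <- graph$succ[s, a]
      v <- total + trial$rewards[s2]
      if (s2 %in% trial$neg) v <- -v
      v
    }, numeric(1))
    a <- graph$actions[which.max(vals)]
    s <- graph$succ[s, a]
    total <- total + trial$rewards[s]
    if (s %in% trial$neg) total <- -total
  }
  total
}

#' Generate a session of trials
#'
#' Draws a sequence of trials: uniform random start state, two distinct
#' uniform random neg states, and rewards that drift by -1/0/+1 pence between
#' consecutive trials (the first trial uses `rewards0`). With
#' `adversarial_filter = TRUE`, the start/neg assignment of each trial is
#' resampled until the best four-move plan out-earns a deterministic greedy
#' chooser by at least `margin` pence, discouraging trials solvable by simple
#' local strategies.
#'
#' @param graph A [task_graph()].
#' @param n_trials Number of trials.
#' @param rewards0 Optional initial rewards (default: uniform on -5..5).
#' @param adversarial_filter Enforce the optimal-minus-greedy margin?
#' @param margin Required margin in pence (default 2).
#' @param max_resamples Resampling budget per trial before erroring.
#' @return A data.frame of class `task_session` with columns `trial`, `start`,
#'   `neg1`, `neg2` and `r1..rn`.
#' @export
generate_session <- function(graph, n_trials, rewards0 = NULL,
                             adversarial_filter = FALSE, margin = 2,
                             max_resamples = 1000L) {
  stopifnot(inherits(graph, "task_graph"))
  .assert(n_trials >= 1, "n_trials must be >= 1")
  n <- graph$n_states
  rewards <- if (is.null(rewards0)) sample(-5:5, n, replace = TRUE)
             else as.integer(rewards0)
  .assert(all(rewards >= -5 & rewards <= 5), "rewards0 must lie in [-5, 5]")
  rows <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    if (t > 1) rewards <- drift_rewards(rewards)
    for (k in seq_len(max_resamples)) {
      start <- sample.int(n, 1)
      neg <- sample.int(n, 2)
      tr <- trial_spec(start, neg, rewards, n)
      if (!adversarial_filter) break
      gap <- max(plan_values(graph, tr)) - .greedy_earnings(graph, tr)
      if (gap >= margin) break
      if (k == max_resamples) {
        stop("adversarial filter failed after ", max_resamples,
             " resamples on trial ", t, call. = FALSE)
      }
    }
    rows[[t]] <- data.frame(trial = t, start = start,
                            neg1 = neg[1], neg2 = neg[2],
                            t(stats::setNames(rewards, paste0("r", seq_len(n)))))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("task_session", "data.frame")
  out
}

#' Extract one trial of a session as a trial_spec
#'
#' @param session A [generate_session()] data.frame.
#' @param t Trial number.
#' @param n_states Number of states.
#' @return A [trial_spec()].
#' @export
session_trial <- function(session, t, n_states = 6L) {
  row <- session[session$trial == t, , drop = FALSE]
  .assert(nrow(row) == 1, "trial %d not found in session", t)
  trial_spec(row$start, c(row$neg1, row$neg2),
             as.integer(row[paste0("r", seq_len(n_states))]), n_states)
}
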