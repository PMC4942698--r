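#' Constrained balanced cross-validation partition
#'
#' Randomly splits labeled trials under three constraints: (1) every class
#' has at least one left-out trial, (2) every class has the same number of
#' left-in trials, and (3) the number of left-out trials is minimal given
#' (1) and (2). These force the left-in count per class to
#' `min(class counts) - 1`; which trials are left out is random.
#'
#' @param labels Class label per trial.
#' @return List with integer index vectors `train` and `test`.
#' @export
balanced_partition <- function(labels) {
  labels <- as.factor(labels)
  counts <- table(labels)
  .assert(all(counts >= 2), "every class needs at least 2 trials")
  keep <- min(counts) - 1L
  train <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    train <- c(train, sample(idx, keep))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Train per-state lasso logistic classifiers
#'
#' One one-vs-rest lasso-penalized logistic regression per state, trained on
#' the single peristimulus sample at `train_latency_ms` (200 ms by default).
#' The L1 penalty applies to the sensor slopes only; the intercept is
#' unpenalized, so for large `lambda` all slopes are exactly zero and the
#' model predicts the class base rate. Each trained model is a weight vector
#' of length `n_sensors + 1` (intercept plus one slope per sensor; 135 at
#' the default 134 sensors).
#'
#' @param epochs Trials x time x sensors array, or a [simulate_localizer()]
#'   result (in which case `labels` and `times_ms` are taken from it).
#' @param labels True state per trial.
#' @param lambda Lasso penalty (>= 0).
#' @param times_ms Peristimulus time of each sample.
#' @param train_latency_ms Training latency (default 200).
#' @return Object of class `state_classifiers`: `beta` (matrix
#'   `(n_sensors + 1) x n_states`, first row the intercepts), `lambda`,
#'   `train_latency_ms`, `n_sensors`.
#' @export
train_state_classifiers <- function(epochs, labels = NULL, lambda,
                                    times_ms = NULL,
                                    train_latency_ms = 200) {
  if (inherits(epochs, "localizer_data")) {
    labels <- epochs$labels
    times_ms <- epochs$times_ms
    epochs <- epochs$epochs
  }
  .assert(lambda >= 0, "lambda must be >= 0")
  .assert(!is.null(labels) && !is.null(times_ms),
          "labels and times_ms are required")
  ti <- which.min(abs(times_ms - train_latency_ms))
  bin <- stats::median(diff(times_ms))
  .assert(abs(times_ms[ti] - train_latency_ms) <= bin / 2 + 1e-9,
          "epochs do not cover the training latency")
  x <- epochs[, ti, , drop = TRUE]
  x <- matrix(x, nrow = dim(epochs)[1])
  .assert(any(apply(x, 2, stats::sd) > 0), "all sensors have zero variance")
  states <- sort(unique(labels))
  K <- length(states)
  p <- ncol(x)
  beta <- matrix(0, p + 1, K,
                 dimnames = list(NULL, paste0("S", states)))
  # decreasing lambda path ending at the target keeps glmnet's warm starts
  lam_path <- sort(unique(c(exp(seq(log(max(lambda, 1e-4) * 100),
                                    log(max(lambda, 1e-6)), length.out = 15)),
                            lambda)), decreasing = TRUE)
  for (k in seq_len(K)) {
    yk <- as.integer(labels == states[k])
    fit <- glmnet::glmnet(x, yk, family = "binomial", alpha = 1,
                          lambda = lam_path, standardize = FALSE,
                          thresh = 1e-8, maxit = 1e5)
    idx <- which.min(abs(fit$lambda - lambda))
    if (abs(fit$lambda[idx] - lambda) < 1e-12 * max(1, lambda)) {
      beta[, k] <- c(fit$a0[idx], as.numeric(fit$beta[, idx]))
    } else {
      beta[, k] <- as.numeric(glmnet::coef.glmnet(fit, s = lambda,
                                                  exact = FALSE))
    }
  }
  structure(list(beta = beta, lambda = lambda,
                 train_latency_ms = train_latency_ms, n_sensors = p,
                 states = states),
            class = "state_classifiers")
}

#' @export
print.state_classifiers <- function(x, ...) {
  nz <- colSums(x$beta[-1, , drop = FALSE] != 0)
  cat(sprintf(
    "<state_classifiers> %d states, %d sensors, lambda = %g, nonzero slopes: %s\n",
    ncol(x$beta), x$n_sensors, x$lambda, paste(nz, collapse = "/")))
  invisible(x)
}

#' Decode sensor data into state probabilities
#'
#' Applies the trained models independently at every time point: the sensor
#' vector is multiplied by each state's weight vector and passed through a
#' sigmoid, giving a time x states matrix `X` of decoded probabilities. The
#' six models are independent, so rows do not in general sum to 1.
#'
#' @param classifiers A [train_state_classifiers()] result.
#' @param data A [sensor_ts()] or a time x sensors matrix.
#' @return Matrix, time x states, entries in (0, 1).
#' @export
predict_state_probabilities <- function(classifiers, data) {
  stopifnot(inherits(classifiers, "state_classifiers"))
  if (inherits(data, "sensor_ts")) data <- data$data
  data <- as.matrix(data)
  .assert(ncol(data) == classifiers$n_sensors,
          "data has %d sensors, classifiers expect %d",
          ncol(data), classifiers$n_sensors)
  sigmoid(cbind(1, data) %*% classifiers$beta)
}

# One full cross-validation pass: average over n_partitions random balanced
# partitions of per-time mean predicted probability (true state x model x
# time) and argmax accuracy over time.
.run_cv <- function(epochs, labels, lambda, times_ms, train_latency_ms,
                    n_partitions) {
  states <- sort(unique(labels))
  K <- length(states)
  n_time <- dim(epochs)[2]
  prob_sum <- array(0, c(K, K, n_time))
  prob_cnt <- array(0, c(K, K, n_time))
  acc_sum <- numeric(n_time)
  for (rep in seq_len(n_partitions)) {
    part <- balanced_partition(labels)
    clf <- train_state_classifiers(
      epochs[part$train, , , drop = FALSE], labels[part$train], lambda,
      times_ms, train_latency_ms)
    correct <- matrix(0, length(part$test), n_time)
    for (ii in seq_along(part$test)) {
      i <- part$test[ii]
      X <- predict_state_probabilities(clf, epochs[i, , , drop = TRUE])
      truth <- match(labels[i], states)
      prob_sum[truth, , ] <- prob_sum[truth, , ] + t(X)
      prob_cnt[truth, , ] <- prob_cnt[truth, , ] + 1
      correct[ii, ] <- (max.col(X, ties.method = "first") == truth)
    }
    acc_sum <- acc_sum + colMeans(correct)
  }
  list(mean_prob = prob_sum / pmax(prob_cnt, 1),
       accuracy = acc_sum / n_partitions)
}

#' Cross-validated decoding report with label-shuffle null
#'
#' Repeats random balanced partitions, training at the fixed latency on the
#' left-in trials and testing at every peristimulus time on the left-out
#' trials. Reports the mean predicted probability per (true state, model,
#' time) and the per-time argmax accuracy (chance = 1/6 for six balanced
#' classes). The null re-runs the identical procedure with shuffled labels;
#' per shuffle, the maximal statistics are the maximum mean probability over
#' states and time and the maximum accuracy over time, and the thresholds
#' are the 95th percentiles over shuffles (p = 0.05, familywise).
#'
#' @inheritParams train_state_classifiers
#' @param n_partitions Partitions averaged per report (default 50).
#' @param n_shuffles Label shuffles for the null (default 100; fewer than 20
#'   triggers a warning).
#' @return List of class `crossval_report`: `mean_prob` (true state x model
#'   x time array), `accuracy` (per time), `times_ms`,
#'   `accuracy_threshold`, `prob_threshold`, `max_accuracy`,
#'   `peak_time_ms`, `shuffle_max_accuracy`, `shuffle_max_prob`,
#'   `significant` (max accuracy above threshold).
#' @export
crossval_report <- function(epochs, labels = NULL, lambda, times_ms = NULL,
                            train_latency_ms = 200, n_partitions = 50L,
                            n_shuffles = 100L) {
  if (inherits(epochs, "localizer_data")) {
    labels <- epochs$labels
    times_ms <- epochs$times_ms
    epochs <- epochs$epochs
  }
  if (n_shuffles < 20) {
    warning("fewer than 20 shuffles: the significance threshold is unstable")
  }
  obs <- .run_cv(epochs, labels, lambda, times_ms, train_latency_ms,
                 n_partitions)
  sh_acc <- numeric(n_shuffles)
  sh_prob <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    null <- .run_cv(epochs, sample(labels), lambda, times_ms,
                    train_latency_ms, n_partitions)
    sh_acc[s] <- max(null$accuracy)
    sh_prob[s] <- max(null$mean_prob)
  }
  acc_thr <- stats::quantile(sh_acc, 0.95, names = FALSE)
  prob_thr <- stats::quantile(sh_prob, 0.95, names = FALSE)
  structure(list(mean_prob = obs$mean_prob, accuracy = obs$accuracy,
                 times_ms = times_ms,
                 accuracy_threshold = acc_thr, prob_threshold = prob_thr,
                 max_accuracy = max(obs$accuracy),
                 peak_time_ms = times_ms[which.max(obs$accuracy)],
                 shuffle_max_accuracy = sh_acc, shuffle_max_prob = sh_prob,
                 significant = max(obs$accuracy) > acc_thr),
            class = "crossval_report")
}

#' Leave-one-subject-out selection of the lasso penalty
#'
#' Given a per-subject, per-penalty table of sequenceness curves, selects for
#' each held-out subject the penalty whose group-mean difference curve over
#' the *other* subjects has the largest absolute value at its extremal lag.
#' The absolute extremum is used because the direction of the effect is not
#' assumed a priori.
#'
#' @param curves Numeric array `subjects x lambdas x lags` of mean
#'   forward-minus-reverse values (see [penalty_curve_table()]).
#' @param lambdas Penalty grid (length = `dim(curves)[2]`).
#' @return List of class `penalty_selection`: `lambda` (named per-subject
#'   choices), `histogram` (table over the grid, one count per subject),
#'   `scores` (subjects x lambdas matrix of held-out criteria).
#' @export
select_penalty <- function(curves, lambdas) {
  .assert(length(dim(curves)) == 3, "curves must be a 3-d array")
  n_sub <- dim(curves)[1]
  .assert(n_sub >= 2, "need at least two subjects")
  .assert(dim(curves)[2] == length(lambdas), "lambda grid mismatch")
  .assert(length(lambdas) >= 1, "empty penalty grid")
  scores <- matrix(0, n_sub, length(lambdas))
  for (s in seq_len(n_sub)) {
    others <- setdiff(seq_len(n_sub), s)
    group <- apply(curves[others, , , drop = FALSE], c(2, 3), mean)
    scores[s, ] <- apply(abs(group), 1, max)
  }
  pick <- apply(scores, 1, which.max)
  lam <- lambdas[pick]
  names(lam) <- if (!is.null(dimnames(curves)[[1]]))
    dimnames(curves)[[1]] else paste0("subject", seq_len(n_sub))
  hist <- table(factor(lam, levels = lambdas))
  structure(list(lambda = lam, histogram = hist, scores = scores,
                 lambdas = lambdas),
            class = "penalty_selection")
}

#' Per-subject, per-penalty sequenceness table
#'
#' Trains each subject's classifiers at every candidate penalty, decodes the
#' subject's planning data, and records the trial-averaged
#' forward-minus-reverse curve. Feeds [select_penalty()].
#'
#' @param subjects List; each element a list with `localizer` (a
#'   [simulate_localizer()] result or compatible) and `planning` (list of
#'   time x sensors matrices or [sensor_ts()] objects).
#' @param lambdas Penalty grid.
#' @param graph A [task_graph()].
#' @param lags_ms Lag grid in ms.
#' @param fs Sampling rate of the planning data.
#' @return Array `subjects x lambdas x lags`.
#' @export
penalty_curve_table <- function(subjects, lambdas, graph,
                                lags_ms = seq(10, 200, by = 10), fs = 100) {
  n_sub <- length(subjects)
  out <- array(0, c(n_sub, length(lambdas), length(lags_ms)),
               dimnames = list(names(subjects), lambdas, lags_ms))
  for (s in seq_len(n_sub)) {
    loc <- subjects[[s]]$localizer
    for (li in seq_along(lambdas)) {
      clf <- train_state_classifiers(loc, lambda = lambdas[li])
      X_list <- lapply(subjects[[s]]$planning, function(ts)
        predict_state_probabilities(clf, ts))
      out[s, li, ] <-
        sequenceness_curves(X_list, graph$T, lags_ms, fs)$mean$diff
    }
  }
  out
}
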