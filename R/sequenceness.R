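#' The lagged sequenceness statistic
#'
#' Given a decoded state-probability matrix `X` (time x states) and the
#' task's transition matrix `T`, sequenceness asks whether state
#' representations tend to follow the task's transitions at a fixed
#' state-to-state lag. `X` is projected one step through the transitions,
#' `X^F = X T` (column j of `X^F` aggregates evidence that a predecessor of
#' state j was just active) and, for each lag, the Pearson correlation between
#' `X^F[, j]` at time `t` and `X[, j]` at time `t + lag` is computed and
#' averaged over states: that is forward sequenceness. Reverse sequenceness
#' uses the reverse transitions `X^R = X T'`. The reported statistic is
#' forward minus reverse at each lag.
#'
#' With this orientation, data containing an explicit forward chain (state
#' `a` at `t`, a successor of `a` at `t + lag`) produce positive forward
#' sequenceness; a unit test pins this sign convention.
#'
#' @name sequenceness_statistic
NULL

# Matrix power for small square matrices.
.matpow <- function(m, k) {
  out <- diag(nrow(m))
  for (i in seq_len(k)) out <- out %*% m
  out
}

#' Project decoded probabilities through the transition matrix
#'
#' @param X Time x states matrix of decoded probabilities.
#' @param Tm Transition matrix (states x states).
#' @param steps Number of transition steps (>= 1).
#' @param reverse Use the reverse transitions (`t(Tm)`)?
#' @return `X %*% Tm^steps` (or `X %*% t(Tm)^steps`).
#' @export
transition_transform <- function(X, Tm, steps = 1L, reverse = FALSE) {
  X <- as.matrix(X)
  .assert(ncol(X) == ncol(Tm), "X and Tm disagree on the number of states")
  .assert(steps >= 1, "steps must be >= 1")
  M <- if (reverse) t(Tm) else Tm
  X %*% .matpow(M, steps)
}

# Pearson correlation defined as 0 when either input has (near-)zero
# variance; inputs are taken as-is (truncated overlap, no padding).
.safe_cor <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa < 1e-12 || sb < 1e-12) return(0)
  stats::cor(a, b)
}

#' Forward/reverse sequenceness across lags
#'
#' @param X Time x states decoded probability matrix (one trial).
#' @param Tm Transition matrix of the task.
#' @param lags_ms Lag grid in ms; must be multiples of the bin (default
#'   10-200 ms in 10 ms steps).
#' @param fs Sampling rate of `X` in Hz (default 100, 10 ms bins).
#' @return Data.frame of class `sequenceness_curve` with columns `lag_ms`,
#'   `forward`, `reverse` and `diff` (= forward - reverse).
#' @export
sequenceness_curve <- function(X, Tm, lags_ms = seq(10, 200, by = 10),
                               fs = 100) {
  X <- as.matrix(X)
  bin <- 1000 / fs
  lag_bins <- lags_ms / bin
  .assert(all(abs(lag_bins - round(lag_bins)) < 1e-9),
          "lags must be multiples of the %g ms bin", bin)
  lag_bins <- as.integer(round(lag_bins))
  n <- nrow(X)
  .assert(n > max(lag_bins) + 2, "trial too short for the requested lags")
  XF <- transition_transform(X, Tm)
  XR <- transition_transform(X, Tm, reverse = TRUE)
  K <- ncol(X)
  fwd <- rev_ <- numeric(length(lag_bins))
  for (li in seq_along(lag_bins)) {
    d <- lag_bins[li]
    i1 <- seq_len(n - d)
    i2 <- i1 + d
    fwd[li] <- mean(vapply(seq_len(K), function(j)
      .safe_cor(XF[i1, j], X[i2, j]), numeric(1)))
    rev_[li] <- mean(vapply(seq_len(K), function(j)
      .safe_cor(XR[i1, j], X[i2, j]), numeric(1)))
  }
  out <- data.frame(lag_ms = lags_ms, forward = fwd, reverse = rev_,
                    diff = fwd - rev_)
  class(out) <- c("sequenceness_curve", "data.frame")
  out
}

#' Mean sequenceness curve over trials
#'
#' Curves are computed per trial and averaged unweighted.
#'
#' @param X_list List of time x states matrices (one per trial).
#' @inheritParams sequenceness_curve
#' @return List with `mean` (a [sequenceness_curve()]) and `trials`
#'   (data.frame with an extra `trial` column).
#' @export
sequenceness_curves <- function(X_list, Tm, lags_ms = seq(10, 200, by = 10),
                                fs = 100) {
  curves <- lapply(X_list, sequenceness_curve, Tm = Tm, lags_ms = lags_ms,
                   fs = fs)
  per_trial <- do.call(rbind, Map(function(cv, i)
    cbind(trial = i, cv), curves, seq_along(curves)))
  mean_curve <- curves[[1]]
  for (col in c("forward", "reverse", "diff")) {
    mean_curve[[col]] <- rowMeans(
      vapply(curves, function(cv) cv[[col]], numeric(length(lags_ms))))
  }
  list(mean = mean_curve, trials = per_trial)
}

#' Explicit-loop oracle for the sequenceness statistic
#'
#' Computes forward-minus-reverse sequenceness at a single lag using only
#' scalar loops over states and time samples -- no matrix products and no
#' calls to [stats::cor()]. Intended as an independent cross-check of
#' [sequenceness_curve()] on small inputs.
#'
#' @param X Time x states matrix (at most a few hundred rows).
#' @param Tm Transition matrix.
#' @param lag_ms Single lag in ms.
#' @param fs Sampling rate in Hz.
#' @return Scalar forward-minus-reverse value.
#' @export
brute_force_sequenceness <- function(X, Tm, lag_ms, fs = 100) {
  d <- as.integer(round(lag_ms / (1000 / fs)))
  n <- nrow(X)
  K <- ncol(X)
  m <- n - d
  corr_loop <- function(a, b) {
    ma <- 0; mb <- 0
    for (t in seq_len(m)) { ma <- ma + a[t]; mb <- mb + b[t] }
    ma <- ma / m; mb <- mb / m
    sab <- 0; saa <- 0; sbb <- 0
    for (t in seq_len(m)) {
      sab <- sab + (a[t] - ma) * (b[t] - mb)
      saa <- saa + (a[t] - ma)^2
      sbb <- sbb + (b[t] - mb)^2
    }
    if (saa < 1e-24 || sbb < 1e-24) return(0)
    sab / sqrt(saa * sbb)
  }
  total <- 0
  for (j in seq_len(K)) {
    xf <- numeric(m); xr <- numeric(m); xl <- numeric(m)
    for (t in seq_len(m)) {
      for (i in seq_len(K)) {
        xf[t] <- xf[t] + Tm[i, j] * X[t, i]
        xr[t] <- xr[t] + Tm[j, i] * X[t, i]
      }
      xl[t] <- X[t + d, j]
    }
    total <- total + corr_loop(xf, xl) - corr_loop(xr, xl)
  }
  total / K
}

#' Un-normalized length-n sequenceness
#'
#' Generalizes the pairwise measure to chains of `n` consecutive states at a
#' common lag. For each state j and lag `d`, the forward value is the sum
#' over time of the product of `X` projected `n-1, n-2, ..., 0` steps through
#' the transitions, taken at staggered times `t, t+d, ..., t+(n-1)d`:
#' for n = 3 this is `sum_t X^FF[t, j] * X^F[t+d, j] * X[t+2d, j]`. Values
#' are un-normalized sums (not correlations), so magnitudes are not
#' comparable across different `n`; compare reliabilities instead.
#'
#' @param X Time x states matrix.
#' @param Tm Transition matrix.
#' @param n Chain length (3, 4 or 5).
#' @param lags_ms Lag grid in ms.
#' @param fs Sampling rate in Hz.
#' @return Data.frame with columns `lag_ms`, `forward`, `reverse`, `diff`.
#' @export
length_n_curve <- function(X, Tm, n, lags_ms = seq(10, 200, by = 10),
                           fs = 100) {
  .assert(n %in% 3:5, "n must be 3, 4 or 5")
  X <- as.matrix(X)
  bin <- 1000 / fs
  lag_bins <- as.integer(round(lags_ms / bin))
  nt <- nrow(X)
  .assert(nt > (n - 1) * max(lag_bins) + 1,
          "trial too short for length-%d chains at the requested lags", n)
  K <- ncol(X)
  proj_f <- lapply((n - 1):0, function(s)
    if (s == 0) X else transition_transform(X, Tm, steps = s))
  proj_r <- lapply((n - 1):0, function(s)
    if (s == 0) X else transition_transform(X, Tm, steps = s, reverse = TRUE))
  val <- function(projs, d) {
    m <- nt - (n - 1) * d
    prod_mat <- projs[[1]][seq_len(m), , drop = FALSE]
    for (step in 2:n) {
      idx <- seq_len(m) + (step - 1) * d
      prod_mat <- prod_mat * projs[[step]][idx, , drop = FALSE]
    }
    mean(colSums(prod_mat))
  }
  fwd <- vapply(lag_bins, function(d) val(proj_f, d), numeric(1))
  rev_ <- vapply(lag_bins, function(d) val(proj_r, d), numeric(1))
  data.frame(lag_ms = lags_ms, forward = fwd, reverse = rev_,
             diff = fwd - rev_)
}

#' Pairwise sequenceness for one ordered state pair
#'
#' The correlation of `X[, i]` at `t` with `X[, j]` at `t + lag` minus the
#' correlation of `X[, j]` at `t` with `X[, i]` at `t + lag`; positive values
#' indicate i-then-j ordering. Antisymmetric by construction:
#' `score(i, j) = -score(j, i)`.
#'
#' @param X Time x states matrix.
#' @param i,j Distinct state indices.
#' @param lag_ms Lag in ms.
#' @param fs Sampling rate in Hz.
#' @return Scalar score.
#' @export
pairwise_sequenceness <- function(X, i, j, lag_ms = 40, fs = 100) {
  .assert(i != j, "i and j must differ")
  d <- as.integer(round(lag_ms / (1000 / fs)))
  n <- nrow(X)
  i1 <- seq_len(n - d)
  i2 <- i1 + d
  .safe_cor(X[i1, i], X[i2, j]) - .safe_cor(X[i1, j], X[i2, i])
}

#' All ordered-pair sequenceness scores
#'
#' @inheritParams pairwise_sequenceness
#' @return Antisymmetric states x states matrix of pair scores (zero
#'   diagonal).
#' @export
pairwise_sequenceness_matrix <- function(X, lag_ms = 40, fs = 100) {
  K <- ncol(X)
  out <- matrix(0, K, K)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      s <- pairwise_sequenceness(X, i, j, lag_ms, fs)
      out[i, j] <- s
      out[j, i] <- -s
    }
  }
  out
}

#' Enumerate state-relabeling classes of a transition matrix
#'
#' Every permutation `sigma` of the state labels induces a permuted matrix
#' `M[a, b] = Tm[sigma[a], sigma[b]]`. Permutations inducing the same matrix
#' are grouped; one representative per distinct matrix is returned, with the
#' identity class (matrix equal to `Tm`) and the reversal class (matrix equal
#' to `t(Tm)`, i.e. all task paths time-reversed) tagged when present. By
#' coset structure all classes have equal size, the order of the matrix's
#' automorphism group.
#'
#' @param Tm Square transition matrix (up to 8 states).
#' @return List: `reps` (list of permutation vectors, one per class),
#'   `class_size`, `n_classes`, `identity_rep` and `reversal_rep` (indices
#'   into `reps`, `NA` if absent).
#' @export
enumerate_label_classes <- function(Tm) {
  K <- ncol(Tm)
  .assert(K <= 8, "enumeration limited to 8 states")
  perms <- .all_perms(K)
  seen <- new.env(parent = emptyenv())
  reps <- list()
  counts <- integer()
  Tt <- t(Tm)
  identity_rep <- NA_integer_
  reversal_rep <- NA_integer_
  for (p in perms) {
    M <- Tm[p, p, drop = FALSE]
    key <- paste(signif(M, 12), collapse = ",")
    idx <- seen[[key]]
    if (is.null(idx)) {
      reps[[length(reps) + 1L]] <- p
      counts[length(reps)] <- 1L
      seen[[key]] <- length(reps)
      idx <- length(reps)
      if (isTRUE(all.equal(M, Tm, check.attributes = FALSE,
                           tolerance = 1e-12))) identity_rep <- idx
      if (isTRUE(all.equal(M, Tt, check.attributes = FALSE,
                           tolerance = 1e-12))) reversal_rep <- idx
    } else {
      counts[idx] <- counts[idx] + 1L
    }
  }
  list(reps = reps, class_size = counts, n_classes = length(reps),
       identity_rep = identity_rep, reversal_rep = reversal_rep)
}

# All permutations of 1..n, deterministic order.
.all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- .all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (s in sub) {
      out[[k]] <- c(first, rest[s])
      k <- k + 1L
    }
  }
  out
}

#' Shuffle-class representatives for the state-identity null
#'
#' The label-relabeling classes of [enumerate_label_classes()] minus the
#' identity and reversal classes; these are the exchangeable shuffles used
#' for non-parametric sequenceness thresholds.
#'
#' @param Tm Transition matrix.
#' @return List of permutation vectors.
#' @export
shuffle_representatives <- function(Tm) {
  cls <- enumerate_label_classes(Tm)
  drop <- stats::na.omit(c(cls$identity_rep, cls$reversal_rep))
  cls$reps[setdiff(seq_along(cls$reps), drop)]
}

# ---- fast paths -----------------------------------------------------------
#
# The permutation nulls re-evaluate the statistic for many transition
# matrices and shuffled trials; compiled kernels (src/seqness.cpp) restate
# the per-lag correlations in terms of segment moments. Tests pin both fast
# paths to sequenceness_curve() and to the explicit-loop oracle.

# diff curve for a single transition matrix; equals sequenceness_curve()$diff.
.diff_curve_fast <- function(X, Tm, lag_bins) {
  .cpp_diff_curve(as.matrix(X), Tm, as.integer(lag_bins))
}

# diff curve values for every permutation at every lag, for a single trial;
# perms are 1-based relabeling vectors (permuted matrix M[a,b] = Tm[p[a],p[b]]).
.seq_diff_perms <- function(X, Tm, perms, lag_bins) {
  .cpp_diff_perms(as.matrix(X), Tm, perms, as.integer(lag_bins))
}

# trial-averaged observed curve via the compiled kernel.
.mean_curve_fast <- function(X_list, Tm, lags_ms, lag_bins) {
  acc <- matrix(0, 2, length(lag_bins))
  for (X in X_list) acc <- acc + .cpp_fr_curve(as.matrix(X), Tm,
                                               as.integer(lag_bins))
  acc <- acc / length(X_list)
  out <- data.frame(lag_ms = lags_ms, forward = acc[1, ],
                    reverse = acc[2, ], diff = acc[1, ] - acc[2, ])
  class(out) <- c("sequenceness_curve", "data.frame")
  out
}

#' State-identity permutation null for the sequenceness curve
#'
#' Recomputes the trial-averaged forward-minus-reverse curve under every
#' shuffle-class representative of the transition matrix (all label
#' relabelings up to the matrix's symmetries, excluding the identity and the
#' reversal classes). The per-lag threshold is the maximum absolute shuffle
#' value at that lag; the global threshold is the maximum over shuffles and
#' lags, controlling family-wise error over the lag grid at a nominal
#' two-tailed level of `1 / n_shuffles`.
#'
#' @param X_list List of decoded probability matrices (trials).
#' @param Tm Transition matrix.
#' @param lags_ms Lag grid in ms.
#' @param fs Sampling rate in Hz.
#' @return List of class `shuffle_null`: `observed` (mean
#'   [sequenceness_curve()]), `shuffle_diff` (matrix shuffles x lags of mean
#'   diff values), `per_lag_threshold`, `global_threshold`, `exceeded`
#'   (logical per lag: `|observed diff| > global_threshold`), `significant`,
#'   `nominal_p` (= `1 / n_shuffles`), `p_value` (add-one empirical p of the
#'   observed peak among shuffle peaks) and `n_shuffles`.
#' @export
permutation_thresholds <- function(X_list, Tm, lags_ms = seq(10, 200, by = 10),
                                   fs = 100) {
  .assert(length(X_list) >= 1, "need at least one trial")
  reps <- shuffle_representatives(Tm)
  n_shuffles <- length(reps)
  if (n_shuffles < 10) {
    warning("only ", n_shuffles,
            " shuffle classes: the permutation threshold is coarse")
  }
  bin <- 1000 / fs
  lag_bins <- as.integer(round(lags_ms / bin))
  acc <- matrix(0, n_shuffles, length(lag_bins))
  for (X in X_list) acc <- acc + .seq_diff_perms(X, Tm, reps, lag_bins)
  shuffle_diff <- acc / length(X_list)
  observed <- .mean_curve_fast(X_list, Tm, lags_ms, lag_bins)
  per_lag <- apply(abs(shuffle_diff), 2, max)
  global <- max(per_lag)
  obs_max <- max(abs(observed$diff))
  shuf_max <- apply(abs(shuffle_diff), 1, max)
  structure(list(observed = observed, shuffle_diff = shuffle_diff,
                 per_lag_threshold = per_lag, global_threshold = global,
                 exceeded = abs(observed$diff) > global,
                 significant = obs_max > global,
                 nominal_p = 1 / n_shuffles,
                 p_value = (1 + sum(shuf_max >= obs_max)) / (1 + n_shuffles),
                 n_shuffles = n_shuffles, lags_ms = lags_ms),
            class = "shuffle_null")
}

#' Sample-order shuffle null (anticonservative under autocorrelation)
#'
#' Builds a null by randomly permuting the time samples of each trial instead
#' of the state identities. This destroys temporal autocorrelation, so on
#' autocorrelated data (as sensor-level MEG is) the null curves are far
#' flatter than the observed one and the test rejects at well above its
#' nominal level. Provided to demonstrate that failure mode; use
#' [permutation_thresholds()] for inference.
#'
#' @inheritParams permutation_thresholds
#' @param n_shuffles Number of sample-order shuffles (default 24).
#' @return List of class `shuffle_null` with the same fields as
#'   [permutation_thresholds()].
#' @export
sample_order_thresholds <- function(X_list, Tm,
                                    lags_ms = seq(10, 200, by = 10),
                                    fs = 100, n_shuffles = 24L) {
  .assert(length(X_list) >= 1, "need at least one trial")
  lag_bins <- as.integer(round(lags_ms / (1000 / fs)))
  observed <- .mean_curve_fast(X_list, Tm, lags_ms, lag_bins)
  shuffle_diff <- matrix(0, n_shuffles, length(lags_ms))
  for (X in X_list) {
    X <- as.matrix(X)
    ord <- vapply(seq_len(n_shuffles), function(s) sample.int(nrow(X)),
                  integer(nrow(X)))
    shuffle_diff <- shuffle_diff +
      .cpp_sample_null(X, Tm, lag_bins, ord)
  }
  shuffle_diff <- shuffle_diff / length(X_list)
  per_lag <- apply(abs(shuffle_diff), 2, max)
  global <- max(per_lag)
  obs_max <- max(abs(observed$diff))
  shuf_max <- apply(abs(shuffle_diff), 1, max)
  structure(list(observed = observed, shuffle_diff = shuffle_diff,
                 per_lag_threshold = per_lag, global_threshold = global,
                 exceeded = abs(observed$diff) > global,
                 significant = obs_max > global,
                 nominal_p = 1 / n_shuffles,
                 p_value = (1 + sum(shuf_max >= obs_max)) / (1 + n_shuffles),
                 n_shuffles = n_shuffles, lags_ms = lags_ms),
            class = "shuffle_null")
}

#' Duration spanned by a chain of states
#'
#' @param n_states Number of states in the chain.
#' @param lag_ms State-to-state lag in ms.
#' @return `(n_states - 1) * lag_ms`: e.g. a 4-state chain at 40 ms lag spans
#'   120 ms.
#' @export
chain_duration_ms <- function(n_states, lag_ms) (n_states - 1) * lag_ms

#' Temporal compression factor
#'
#' Ratio of a real-experience state-transition duration to the
#' state-to-state lag of spontaneous sequences.
#'
#' @param reference_ms Real transition duration in ms (e.g. the 350 ms
#'   visual cross-fade).
#' @param lag_ms Sequence state-to-state lag in ms.
#' @return `reference_ms / lag_ms`.
#' @export
temporal_compression <- function(reference_ms, lag_ms) reference_ms / lag_ms

#' Nominal two-tailed level of a maximal-statistic shuffle test
#'
#' @param n_shuffles Number of exchangeable shuffles.
#' @return `1 / n_shuffles` (e.g. 28 shuffles give about 0.036).
#' @export
shuffle_nominal_level <- function(n_shuffles) 1 / n_shuffles
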