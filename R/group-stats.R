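#' Random-intercept mixed model for trial-level statistics
#'
#' Fits `y_i = beta + b_k + e_i` by maximum likelihood, where `k` indexes
#' subjects and the subject intercepts `b_k` are Gaussian with standard
#' deviation `sigma_b`. This is the group-level test applied to trial-wise
#' sequenceness values: `beta` estimates the population mean and its Wald
#' normal two-tailed p tests it against zero. An optional trial-level
#' covariate adds a single fixed slope to the same model (used for
#' regressions of sequenceness on earnings or planning time).
#'
#' With a single subject the model is degenerate and the function falls back
#' to a one-sample t-test with a warning.
#'
#' @param y Numeric vector of trial-level values.
#' @param subject Subject id per observation.
#' @param x Optional numeric covariate per observation.
#' @return List of class `mixed_fit`: `beta`, `se`, `z`, `p`, `sigma_b`,
#'   `sigma_e`, `log_lik`, `n_obs`, `n_subjects`, and when `x` is given also
#'   `slope`, `slope_se`, `slope_z`, `slope_p`.
#' @export
mixed_intercept_fit <- function(y, subject, x = NULL) {
  .assert(length(y) >= 2, "need at least two observations")
  subject <- as.factor(subject)
  if (nlevels(subject) < 2) {
    warning("single subject: falling back to a one-sample t-test")
    tt <- stats::t.test(y)
    out <- list(beta = unname(tt$estimate), se = tt$stderr,
                z = unname(tt$statistic), p = tt$p.value,
                sigma_b = 0, sigma_e = stats::sd(y),
                log_lik = NA_real_, n_obs = length(y), n_subjects = 1L)
    class(out) <- "mixed_fit"
    return(out)
  }
  if (max(table(subject)) == 1L) {
    # one observation per subject: sigma_b and sigma_e are confounded and
    # the model collapses to an ordinary location test / regression
    warning("one observation per subject: subject and residual variance ",
            "are confounded; using the collapsed model")
    if (is.null(x)) {
      tt <- stats::t.test(y)
      out <- list(beta = unname(tt$estimate), se = tt$stderr,
                  z = unname(tt$statistic), p = tt$p.value,
                  sigma_b = 0, sigma_e = stats::sd(y),
                  log_lik = NA_real_, n_obs = length(y),
                  n_subjects = nlevels(subject))
    } else {
      lmfit <- stats::lm(y ~ x)
      co <- summary(lmfit)$coefficients
      out <- list(beta = co[1, 1], se = co[1, 2], z = co[1, 3], p = co[1, 4],
                  sigma_b = 0, sigma_e = summary(lmfit)$sigma,
                  log_lik = as.numeric(stats::logLik(lmfit)),
                  n_obs = length(y), n_subjects = nlevels(subject),
                  slope = co[2, 1], slope_se = co[2, 2], slope_z = co[2, 3],
                  slope_p = co[2, 4])
    }
    class(out) <- "mixed_fit"
    return(out)
  }
  df <- data.frame(y = y, subject = subject)
  form <- y ~ 1 + (1 | subject)
  if (!is.null(x)) {
    df$x <- x
    form <- y ~ x + (1 | subject)
  }
  fit <- lme4::lmer(form, data = df, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_b <- vc$sdcor[vc$grp == "subject"]
  sigma_e <- vc$sdcor[vc$grp == "Residual"]
  z <- fe[["(Intercept)"]] / se[[1]]
  out <- list(beta = fe[["(Intercept)"]], se = se[[1]], z = z,
              p = 2 * stats::pnorm(-abs(z)),
              sigma_b = sigma_b, sigma_e = sigma_e,
              log_lik = as.numeric(stats::logLik(fit)),
              n_obs = length(y), n_subjects = nlevels(subject))
  if (!is.null(x)) {
    zs <- fe[["x"]] / se[[2]]
    out$slope <- fe[["x"]]
    out$slope_se <- se[[2]]
    out$slope_z <- zs
    out$slope_p <- 2 * stats::pnorm(-abs(zs))
  }
  class(out) <- "mixed_fit"
  out
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf(
    "<mixed_fit> beta = %.4g (SE %.3g, z = %.2f, p = %.3g), sigma_b = %.3g, sigma_e = %.3g\n",
    x$beta, x$se, x$z, x$p, x$sigma_b, x$sigma_e))
  if (!is.null(x$slope)) {
    cat(sprintf("  slope = %.4g (SE %.3g, p = %.3g)\n",
                x$slope, x$slope_se, x$slope_p))
  }
  invisible(x)
}

#' Chosen-versus-unchosen tuple contrast
#'
#' On each trial the chosen four-move plan traverses four directed state
#' pairs (tuples). This contrast asks whether the pairwise sequenceness of
#' the chosen tuples exceeds that of the unchosen task edges: the per-trial
#' statistic is mean(chosen pair scores) - mean(unchosen pair scores), and
#' group inference applies [mixed_intercept_fit()] to the trial contrasts.
#' In `"first_move"` mode only the first chosen tuple counts as chosen (1
#' chosen vs 11 unchosen edges on the default maze).
#'
#' @param pair_scores Data.frame with columns `subject`, `trial`, `from`,
#'   `to`, `score` giving pairwise sequenceness per directed task edge and
#'   trial (see [pairwise_sequenceness_matrix()]).
#' @param choices Data.frame with columns `subject`, `trial`, `start`,
#'   `move1..move4`.
#' @param graph A [task_graph()].
#' @param mode `"all_moves"` (default) or `"first_move"`.
#' @return List of class `tuple_contrast`: `trials` (per-trial contrasts)
#'   and `fit` (the group [mixed_intercept_fit()]).
#' @export
tuple_contrast <- function(pair_scores, choices, graph,
                           mode = c("all_moves", "first_move")) {
  mode <- match.arg(mode)
  edges <- task_edges(graph)
  edge_key <- paste(edges[, "from"], edges[, "to"], sep = ">")
  move_cols <- paste0("move", 1:4)
  rows <- vector("list", nrow(choices))
  for (r in seq_len(nrow(choices))) {
    ch <- choices[r, ]
    if (any(is.na(ch[move_cols]))) {
      message("skipping trial ", ch$trial, " of subject ", ch$subject,
              ": missing choices")
      next
    }
    s <- ch$start
    chosen <- character(0)
    for (m in move_cols) {
      s2 <- graph$succ[s, as.character(ch[[m]])]
      chosen <- c(chosen, paste(s, s2, sep = ">"))
      s <- s2
    }
    if (mode == "first_move") chosen <- chosen[1]
    ps <- pair_scores[pair_scores$subject == ch$subject &
                        pair_scores$trial == ch$trial, ]
    key <- paste(ps$from, ps$to, sep = ">")
    sc <- stats::setNames(ps$score, key)[edge_key]
    is_chosen <- edge_key %in% chosen
    rows[[r]] <- data.frame(
      subject = ch$subject, trial = ch$trial,
      chosen_mean = mean(sc[is_chosen]),
      unchosen_mean = mean(sc[!is_chosen]),
      n_chosen = sum(is_chosen), n_unchosen = sum(!is_chosen))
  }
  trials <- do.call(rbind, rows)
  trials$contrast <- trials$chosen_mean - trials$unchosen_mean
  fit <- mixed_intercept_fit(trials$contrast, trials$subject)
  structure(list(trials = trials, fit = fit, mode = mode),
            class = "tuple_contrast")
}

#' Regression on subject means
#'
#' Ordinary least squares of one subject-level summary on another, as used
#' for between-subject correlations (planning time, earnings, sequenceness).
#'
#' @param x,y Numeric vectors of subject means (length >= 3).
#' @return List: `slope`, `se`, `t`, `p` (two-tailed), `intercept`, `n`.
#' @export
subject_mean_regression <- function(x, y) {
  .assert(length(x) == length(y) && length(x) >= 3,
          "need at least three paired subject means")
  .assert(stats::sd(x) > 0, "x has zero variance")
  fit <- stats::lm(y ~ x)
  co <- summary(fit)$coefficients
  list(slope = co["x", "Estimate"], se = co["x", "Std. Error"],
       t = co["x", "t value"], p = co["x", "Pr(>|t|)"],
       intercept = co["(Intercept)", "Estimate"], n = length(x))
}

#' One-way ANOVA across directed task-edge pairs
#'
#' Tests whether mean pairwise sequenceness differs between the directed
#' edges of the task (12 on the default maze) across sessions. With 12 pairs
#' and 12 sessions the F statistic has (11, 132) degrees of freedom.
#'
#' @param scores Data.frame with columns `pair` (group label) and `value`.
#' @return List: `F`, `df1`, `df2`, `p`.
#' @export
pair_anova <- function(scores) {
  .assert(all(c("pair", "value") %in% names(scores)),
          "scores needs columns pair and value")
  counts <- table(scores$pair)
  .assert(length(counts) >= 2 && all(counts >= 2),
          "need >= 2 groups with >= 2 observations each")
  fit <- stats::lm(value ~ factor(pair), data = scores)
  a <- stats::anova(fit)
  list(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
       p = a$`Pr(>F)`[1])
}
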