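#' Default pipeline configuration
#'
#' Builds the nested configuration driving [run_pipeline()]. All values are
#' overridable; anything omitted keeps its default. The `synthetic` section
#' accepts the arguments of [synth_config()] plus `n_localizer_trials_per_state`
#' and `n_planning_trials`.
#'
#' @param ... Named top-level overrides, merged into the defaults (one level
#'   deep for the stage sub-lists).
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    n_subjects = 12L,
    task = list(edges = NULL),
    synthetic = list(n_localizer_trials_per_state = 16L,
                     n_planning_trials = 4L),
    preprocess = list(highpass = FALSE, cutoff_hz = 0.5, zero_phase = TRUE),
    decoder = list(lambda = 0.006, train_latency_ms = 200),
    sequenceness = list(lags_ms = seq(10, 200, by = 10)),
    behavior = list(enabled = TRUE, n_trials = 100, model = "Plan",
                    beta = 0.3, alpha = 0.3),
    output = list(write_h5 = FALSE)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(defaults[[nm]])) {
      for (k in names(over[[nm]])) defaults[[nm]][[k]] <- over[[nm]][[k]]
    } else {
      defaults[[nm]] <- over[[nm]]
    }
  }
  structure(defaults, class = c("pipeline_config", "list"))
}

# synth_config from the synthetic section, dropping pipeline-only fields.
.config_synth <- function(cfg) {
  args <- cfg$synthetic
  args$n_localizer_trials_per_state <- NULL
  args$n_planning_trials <- NULL
  if (!is.null(args$length_dist)) {
    args$length_dist <- stats::setNames(as.numeric(args$length_dist),
                                        names(args$length_dist))
  }
  do.call(synth_config, args)
}

#' Run the full simulate-decode-detect pipeline
#'
#' For each synthetic subject: draw state patterns, simulate a localizer run
#' and planning periods with planted replay, optionally high-pass filter,
#' train per-state lasso classifiers at the configured penalty, decode the
#' planning data, and compute per-trial sequenceness curves. Group-level
#' results comprise the trial-averaged curve, its state-identity permutation
#' thresholds, and a random-intercept model of the per-trial
#' forward-minus-reverse values at the extremal lag of the group curve.
#' Optionally simulates and fits the behavioral choice models.
#'
#' The run is fully determined by `config$seed`: the seed is expanded into
#' independent per-stage streams, so reruns with the same configuration give
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `curves.csv`, `trial_diff.csv`, `summary.json`, `report.txt`,
#'   `config.yaml` and (if `output$write_h5`) per-subject HDF5 containers.
#' @return List of class `pipeline_result` (invisibly when writing): per
#'   subject data, group curve, `null` (a `shuffle_null`), `mixed`
#'   (a [mixed_intercept_fit()]), `behavior`, `event_table`, `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  stage_seeds <- .spawn_seeds(config$n_subjects + 2L)
  graph <- task_graph(config$task$edges)
  scfg <- .config_synth(config)
  lags_ms <- config$sequenceness$lags_ms

  subjects <- vector("list", config$n_subjects)
  all_X <- list()
  curve_rows <- list()
  event_rows <- list()
  for (s in seq_len(config$n_subjects)) {
    set.seed(stage_seeds[s])
    patterns <- make_state_patterns(scfg$n_states, scfg$n_sensors)
    loc <- simulate_localizer(
      scfg, patterns, config$synthetic$n_localizer_trials_per_state)
    planning <- lapply(seq_len(config$synthetic$n_planning_trials),
                       function(t) {
      dur <- stats::runif(1, scfg$planning_duration_s[1],
                          scfg$planning_duration_s[2])
      simulate_planning(scfg, patterns, graph, dur)
    })
    ts_list <- lapply(planning, `[[`, "ts")
    if (isTRUE(config$preprocess$highpass)) {
      spec <- filter_spec(config$preprocess$cutoff_hz,
                          config$preprocess$zero_phase)
      ts_list <- lapply(ts_list, highpass, spec = spec)
    }
    clf <- train_state_classifiers(
      loc, lambda = config$decoder$lambda,
      train_latency_ms = config$decoder$train_latency_ms)
    X_list <- lapply(ts_list, predict_state_probabilities,
                     classifiers = clf)
    curves <- sequenceness_curves(X_list, graph$T, lags_ms, scfg$fs)
    subjects[[s]] <- list(classifiers = clf, curves = curves,
                          planning = planning, X = X_list)
    all_X <- c(all_X, X_list)
    curve_rows[[s]] <- cbind(subject = s, curves$trials)
    ev <- do.call(rbind, lapply(planning, `[[`, "events"))
    if (nrow(ev) > 0) event_rows[[s]] <- cbind(subject = s, ev)
  }

  set.seed(stage_seeds[config$n_subjects + 1L])
  null <- permutation_thresholds(all_X, graph$T, lags_ms, scfg$fs)
  group_curve <- null$observed
  extremal_lag <- group_curve$lag_ms[which.max(abs(group_curve$diff))]

  curves_df <- do.call(rbind, curve_rows)
  at_lag <- curves_df[curves_df$lag_ms == extremal_lag, ]
  mixed <- mixed_intercept_fit(at_lag$diff, at_lag$subject)

  behavior <- NULL
  if (isTRUE(config$behavior$enabled)) {
    set.seed(stage_seeds[config$n_subjects + 2L])
    session <- generate_session(graph, config$behavior$n_trials)
    choices <- simulate_choices(
      config$behavior$model,
      list(beta = config$behavior$beta, alpha = config$behavior$alpha),
      graph, session)
    comparison <- fit_and_compare(choices, graph, session)
    behavior <- list(session = session, choices = choices,
                     comparison = comparison)
  }

  event_table <- if (length(event_rows) > 0) do.call(rbind, event_rows) else
    data.frame()
  events_by_dir <- if (nrow(event_table) > 0)
    as.list(table(event_table$direction)) else list()

  summary <- list(
    n_subjects = config$n_subjects,
    n_trials = length(all_X),
    lambda = config$decoder$lambda,
    extremal_lag_ms = extremal_lag,
    diff_at_extremal = group_curve$diff[group_curve$lag_ms == extremal_lag],
    global_threshold = null$global_threshold,
    significant = null$significant,
    n_shuffles = null$n_shuffles,
    nominal_p = null$nominal_p,
    mixed_beta = mixed$beta, mixed_p = mixed$p,
    planted_events = events_by_dir,
    behavior_best = if (!is.null(behavior))
      behavior$comparison$model[1] else NA_character_
  )

  result <- structure(
    list(config = config, graph = graph, subjects = subjects,
         group_curve = group_curve, null = null, mixed = mixed,
         behavior = behavior, event_table = event_table,
         curves = curves_df, summary = summary),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(curves_df, file.path(out_dir, "curves.csv"),
                     row.names = FALSE)
    utils::write.csv(at_lag, file.path(out_dir, "trial_diff.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(make_report(result), file.path(out_dir, "report.txt"))
    write_config(unclass(config), file.path(out_dir, "config.yaml"))
    if (isTRUE(config$output$write_h5)) {
      for (s in seq_along(subjects)) {
        sd <- file.path(out_dir, sprintf("subject_%02d", s))
        dir.create(sd, showWarnings = FALSE)
        for (t in seq_along(subjects[[s]]$planning)) {
          pl <- subjects[[s]]$planning[[t]]
          write_sensor_h5(pl$ts,
                          file.path(sd, sprintf("planning_%02d.h5", t)),
                          ground_truth = pl$events)
        }
        write_classifiers_h5(subjects[[s]]$classifiers,
                             file.path(sd, "classifiers.h5"))
      }
    }
    return(invisible(result))
  }
  result
}

#' Human-readable pipeline report
#'
#' @param result A [run_pipeline()] result.
#' @return Character vector of report lines (also usable with
#'   [writeLines()]).
#' @export
make_report <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  s <- result$summary
  lines <- c(
    "== sequenceness pipeline report ==",
    sprintf("subjects: %d, planning trials: %d, lasso penalty: %g",
            s$n_subjects, s$n_trials, s$lambda),
    "",
    "-- group sequenceness (forward - reverse) --",
    sprintf("extremal lag: %g ms, value %.5f", s$extremal_lag_ms,
            s$diff_at_extremal),
    sprintf("global shuffle threshold (%d state-identity shuffles): %.5f",
            s$n_shuffles, s$global_threshold),
    sprintf("significant at nominal two-tailed p = %.3f: %s", s$nominal_p,
            if (isTRUE(s$significant)) "YES" else "no"),
    sprintf("mixed intercept model: beta = %.5g, p = %.3g",
            s$mixed_beta, s$mixed_p),
    "",
    "-- planted events (ground truth) --")
  if (nrow(result$event_table) > 0) {
    tab <- table(result$event_table$direction, result$event_table$length)
    for (d in rownames(tab)) {
      lines <- c(lines, sprintf("  %s: %s", d,
        paste(sprintf("length %s: %d", colnames(tab), tab[d, ]),
              collapse = ", ")))
    }
  } else {
    lines <- c(lines, "  none (no significant sequenceness expected)")
  }
  if (!is.null(result$behavior)) {
    lines <- c(lines, "", "-- behavioral model comparison (BIC) --")
    cmp <- result$behavior$comparison
    lines <- c(lines, utils::capture.output(print(
      format(cmp[, c("model", "log_likelihood", "n_params", "bic")],
             digits = 4), row.names = FALSE)))
  }
  if (!isTRUE(s$significant)) {
    lines <- c(lines, "", "NOTE: no significant sequenceness detected.")
  }
  lines
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `decode`, `seqness`, `permtest`, `behavior`,
#' `report`, `run-all`. All read a YAML configuration (`--config`, optional)
#' and write into `--out` (default `seqness_out`). `--seed` overrides the
#' config seed. `run-all` executes the full pipeline; `simulate` writes the
#' per-subject HDF5 containers only; the remaining stages re-run the
#' pipeline deterministically and emit that stage's outputs (stages are
#' cheap relative to simulation and re-derivable from the seed).
#'
#' @param args Character vector of command-line arguments (default: the
#'   process arguments).
#' @return Exit status, invisibly (0 on success).
#' @export
seqness_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: seqness <simulate|decode|seqness|permtest|behavior|report|run-all>",
    "[--config FILE] [--out DIR] [--seed N]")
  if (length(args) < 1) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  out_dir <- opt("--out", "seqness_out")
  cfg_path <- opt("--config", NA)
  config <- if (!is.na(cfg_path)) do.call(pipeline_config, read_config(cfg_path))
            else pipeline_config()
  seed <- opt("--seed", NA)
  if (!is.na(seed)) config$seed <- as.integer(seed)

  if (cmd == "run-all") {
    run_pipeline(config, out_dir)
  } else if (cmd == "simulate") {
    config$output$write_h5 <- TRUE
    config$behavior$enabled <- FALSE
    run_pipeline(config, out_dir)
  } else if (cmd %in% c("decode", "seqness", "permtest")) {
    res <- run_pipeline(config, NULL)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (cmd == "decode") {
      probs <- do.call(rbind, lapply(seq_along(res$subjects), function(s)
        do.call(rbind, lapply(seq_along(res$subjects[[s]]$X), function(t)
          cbind(subject = s, probabilities_long(
            res$subjects[[s]]$X[[t]], trial = t,
            fs = .config_synth(config)$fs))))))
      utils::write.csv(probs, file.path(out_dir, "probabilities.csv"),
                       row.names = FALSE)
    } else if (cmd == "seqness") {
      utils::write.csv(res$curves, file.path(out_dir, "curves.csv"),
                       row.names = FALSE)
    } else {
      jsonlite::write_json(
        list(per_lag_threshold = res$null$per_lag_threshold,
             global_threshold = res$null$global_threshold,
             nominal_p = res$null$nominal_p,
             significant = res$null$significant,
             shuffles = lapply(
               shuffle_representatives(res$graph$T), as.integer)),
        file.path(out_dir, "permtest.json"), auto_unbox = TRUE, digits = NA)
    }
  } else if (cmd == "behavior") {
    config$behavior$enabled <- TRUE
    res <- run_pipeline(config, NULL)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$behavior$comparison,
                     file.path(out_dir, "behavior.csv"), row.names = FALSE)
  } else if (cmd == "report") {
    res <- run_pipeline(config, NULL)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(make_report(res), file.path(out_dir, "report.txt"))
  } else {
    message(usage)
    return(invisible(1L))
  }
  invisible(0L)
}
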