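#' Write a sensor time series to an HDF5 container
#'
#' Layout: `/data` (time x sensors), `/fs`, `/markers/sample`,
#' `/markers/label`, and optionally `/ground_truth/<column>` for a planted
#' replay event table.
#'
#' @param ts A [sensor_ts()].
#' @param path Output `.h5` file (overwritten).
#' @param ground_truth Optional event data.frame (see [simulate_planning()]).
#' @return `path`, invisibly.
#' @export
write_sensor_h5 <- function(ts, path, ground_truth = NULL) {
  stopifnot(inherits(ts, "sensor_ts"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(ts$data, path, "data")
  rhdf5::h5write(ts$fs, path, "fs")
  rhdf5::h5createGroup(path, "markers")
  rhdf5::h5write(as.integer(ts$markers$sample), path, "markers/sample")
  rhdf5::h5write(as.character(ts$markers$label), path, "markers/label")
  if (!is.null(ground_truth)) {
    rhdf5::h5createGroup(path, "ground_truth")
    for (col in names(ground_truth)) {
      rhdf5::h5write(ground_truth[[col]], path,
                     paste0("ground_truth/", col))
    }
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a sensor time series from an HDF5 container
#'
#' @param path File written by [write_sensor_h5()].
#' @return List with `ts` (a [sensor_ts()]) and `ground_truth` (data.frame
#'   or `NULL`).
#' @export
read_sensor_h5 <- function(path) {
  data <- rhdf5::h5read(path, "data")
  fs <- as.numeric(rhdf5::h5read(path, "fs"))
  markers <- data.frame(
    sample = as.integer(rhdf5::h5read(path, "markers/sample")),
    label = as.character(rhdf5::h5read(path, "markers/label")))
  gt <- NULL
  contents <- rhdf5::h5ls(path)
  if ("ground_truth" %in% contents$name) {
    cols <- contents$name[contents$group == "/ground_truth"]
    gt <- as.data.frame(lapply(stats::setNames(cols, cols), function(col)
      as.vector(rhdf5::h5read(path, paste0("ground_truth/", col)))))
  }
  rhdf5::h5closeAll()
  list(ts = sensor_ts(data, fs, markers), ground_truth = gt)
}

#' Serialize trained classifiers to HDF5
#'
#' Layout: `/state_<k>/beta` (length `n_sensors + 1`, intercept first) and
#' `/state_<k>/lambda` per state, plus `/train_latency_ms`.
#'
#' @param classifiers A [train_state_classifiers()] result.
#' @param path Output `.h5` file (overwritten).
#' @return `path`, invisibly.
#' @export
write_classifiers_h5 <- function(classifiers, path) {
  stopifnot(inherits(classifiers, "state_classifiers"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  for (k in seq_len(ncol(classifiers$beta))) {
    grp <- paste0("state_", classifiers$states[k])
    rhdf5::h5createGroup(path, grp)
    rhdf5::h5write(classifiers$beta[, k], path, paste0(grp, "/beta"))
    rhdf5::h5write(classifiers$lambda, path, paste0(grp, "/lambda"))
  }
  rhdf5::h5write(classifiers$train_latency_ms, path, "train_latency_ms")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read classifiers serialized by [write_classifiers_h5()]
#'
#' @param path `.h5` file.
#' @return A `state_classifiers` object.
#' @export
read_classifiers_h5 <- function(path) {
  contents <- rhdf5::h5ls(path)
  groups <- sort(contents$name[grepl("^state_", contents$name)])
  states <- as.integer(sub("state_", "", groups))
  ord <- order(states)
  beta <- vapply(groups[ord], function(g)
    as.numeric(rhdf5::h5read(path, paste0(g, "/beta"))),
    numeric(length(rhdf5::h5read(path, paste0(groups[1], "/beta")))))
  lambda <- as.numeric(rhdf5::h5read(path, paste0(groups[1], "/lambda")))
  latency <- as.numeric(rhdf5::h5read(path, "train_latency_ms"))
  rhdf5::h5closeAll()
  structure(list(beta = beta, lambda = lambda,
                 train_latency_ms = latency, n_sensors = nrow(beta) - 1L,
                 states = sort(states)),
            class = "state_classifiers")
}

#' Write/read localizer epochs to HDF5
#'
#' Layout: `/epochs` (trials x time x sensors), `/times_ms`, `/labels`.
#'
#' @param loc A [simulate_localizer()] result (or compatible list).
#' @param path `.h5` file.
#' @return `write_localizer_h5` returns `path` invisibly;
#'   `read_localizer_h5` returns a `localizer_data` list.
#' @export
write_localizer_h5 <- function(loc, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(loc$epochs, path, "epochs")
  rhdf5::h5write(loc$times_ms, path, "times_ms")
  rhdf5::h5write(as.integer(loc$labels), path, "labels")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_localizer_h5
#' @export
read_localizer_h5 <- function(path) {
  out <- list(epochs = rhdf5::h5read(path, "epochs"),
              times_ms = as.numeric(rhdf5::h5read(path, "times_ms")),
              labels = as.integer(rhdf5::h5read(path, "labels")))
  rhdf5::h5closeAll()
  class(out) <- "localizer_data"
  out
}

#' Decoded probabilities in long format
#'
#' @param X Time x states probability matrix.
#' @param trial Trial id to attach.
#' @param fs Sampling rate in Hz.
#' @return Data.frame with columns `trial`, `time_ms`, `state`,
#'   `probability`.
#' @export
probabilities_long <- function(X, trial = 1L, fs = 100) {
  K <- ncol(X)
  n <- nrow(X)
  data.frame(trial = trial,
             time_ms = rep((seq_len(n) - 1) * 1000 / fs, K),
             state = rep(seq_len(K), each = n),
             probability = as.vector(X))
}

#' Tidy export of sequenceness curves
#'
#' @param curves The `trials` element of [sequenceness_curves()].
#' @param subject Subject id to attach.
#' @return Data.frame with columns `subject`, `trial`, `lag_ms`, `forward`,
#'   `reverse`, `diff`.
#' @export
curves_long <- function(curves, subject = 1L) {
  cbind(subject = subject, curves)
}

#' Read/write pipeline configuration as YAML
#'
#' @param config Nested configuration list.
#' @param path YAML file path.
#' @return `read_config` returns the list; `write_config` returns `path`
#'   invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
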