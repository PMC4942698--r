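#' High-pass filter specification
#'
#' First-order IIR high-pass, 0.5 Hz cutoff by default, matching the minimal
#' drift-removal used on the real recordings. By default the filter is applied
#' zero-phase (forward-backward): lagged cross-correlation statistics are
#' sensitive to phase shifts, so the phase-neutral mode is the safer default;
#' a causal single-pass mode is available.
#'
#' @param cutoff_hz Cutoff frequency (default 0.5).
#' @param zero_phase Apply forward-backward (default) or causally.
#' @return List of class `filter_spec` (`order` is fixed at 1).
#' @export
filter_spec <- function(cutoff_hz = 0.5, zero_phase = TRUE) {
  .assert(cutoff_hz > 0, "cutoff must be positive")
  structure(list(cutoff_hz = cutoff_hz, order = 1L, zero_phase = zero_phase),
            class = "filter_spec")
}

# Windowed-sinc (Hamming) FIR low-pass with unit DC gain.
.fir_lowpass <- function(cutoff_hz, fs, n_taps) {
  .assert(n_taps %% 2 == 1, "n_taps must be odd")
  m <- (n_taps - 1) / 2
  t <- seq(-m, m)
  fc <- cutoff_hz / fs
  h <- 2 * fc * sinc(2 * fc * t)
  w <- 0.54 + 0.46 * cos(pi * t / m)
  h <- h * w
  h / sum(h)
}

#' Normalized sinc
#' @param x Numeric vector.
#' @return `sin(pi x) / (pi x)` with `sinc(0) = 1`.
#' @keywords internal
sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Symmetric FIR convolution with reflective edge padding, per column.
.apply_fir <- function(x, kernel) {
  m <- (length(kernel) - 1) / 2
  n <- nrow(x)
  pad_top <- x[pmin(m, n - 1):1 + 1, , drop = FALSE]
  pad_bot <- x[n - seq_len(min(m, n - 1)), , drop = FALSE]
  xp <- rbind(pad_top, x, pad_bot)
  y <- stats::filter(xp, kernel, method = "convolution", sides = 2)
  y <- as.matrix(y)
  npad <- nrow(pad_top)
  y[npad + seq_len(n), , drop = FALSE]
}

#' Anti-aliased downsampling
#'
#' Low-pass filters at 0.8 times the new Nyquist frequency with a linear-phase
#' windowed-sinc FIR, then decimates by the integer factor `fs / target_fs`.
#' Markers are re-indexed to the nearest retained sample.
#'
#' @param ts A [sensor_ts()].
#' @param target_fs New sampling rate; `ts$fs` must be an integer multiple.
#' @return A [sensor_ts()] at `target_fs`.
#' @export
downsample <- function(ts, target_fs) {
  stopifnot(inherits(ts, "sensor_ts"))
  q <- ts$fs / target_fs
  .assert(abs(q - round(q)) < 1e-9 && q >= 1,
          "fs (%g) must be an integer multiple of target_fs (%g)",
          ts$fs, target_fs)
  q <- as.integer(round(q))
  if (q == 1L) return(ts)
  kernel <- .fir_lowpass(0.8 * target_fs / 2, ts$fs, n_taps = 60L * q + 1L)
  y <- .apply_fir(ts$data, kernel)
  keep <- seq(1, nrow(y), by = q)
  markers <- ts$markers
  if (nrow(markers) > 0) {
    markers$sample <- pmin(pmax(round((markers$sample - 1) / q) + 1, 1),
                           length(keep))
  }
  sensor_ts(y[keep, , drop = FALSE], target_fs, markers)
}

# First-order high-pass coefficients by bilinear transform of an RC filter:
# y[n] = b0 x[n] + b1 x[n-1] + a1 y[n-1].
.hp_coeffs <- function(cutoff_hz, fs) {
  c0 <- tan(pi * cutoff_hz / fs)
  list(b0 = 1 / (1 + c0), b1 = -1 / (1 + c0), a1 = (1 - c0) / (1 + c0))
}

# One causal pass of the first-order high-pass over the columns of x.
.hp_pass <- function(x, co) {
  n <- nrow(x)
  xl <- rbind(x[1, , drop = FALSE], x[-n, , drop = FALSE])
  v <- co$b0 * x + co$b1 * xl
  y <- apply(v, 2, function(col)
    stats::filter(col, co$a1, method = "recursive", init = 0))
  matrix(y, nrow = n)
}

#' First-order IIR high-pass filter
#'
#' Removes slow drift (and DC) per sensor. In zero-phase mode the data are
#' reflect-padded by three filter time constants at each end, filtered
#' forward and backward, and trimmed, so the passband incurs no phase shift.
#'
#' @param ts A [sensor_ts()].
#' @param spec A [filter_spec()].
#' @return Filtered [sensor_ts()].
#' @export
highpass <- function(ts, spec = filter_spec()) {
  stopifnot(inherits(ts, "sensor_ts"), inherits(spec, "filter_spec"))
  .assert(spec$cutoff_hz < ts$fs / 2, "cutoff must be below Nyquist")
  co <- .hp_coeffs(spec$cutoff_hz, ts$fs)
  x <- ts$data
  n <- nrow(x)
  if (!spec$zero_phase) {
    y <- .hp_pass(x, co)
  } else {
    m <- min(n - 1, ceiling(3 * ts$fs / spec$cutoff_hz))
    pad_top <- x[(m + 1):2, , drop = FALSE]
    pad_bot <- x[n - seq_len(m), , drop = FALSE]
    xp <- rbind(pad_top, x, pad_bot)
    y <- .hp_pass(xp, co)
    y <- .hp_pass(y[nrow(y):1, , drop = FALSE], co)
    y <- y[nrow(y):1, , drop = FALSE]
    y <- y[m + seq_len(n), , drop = FALSE]
  }
  sensor_ts(y, ts$fs, ts$markers)
}
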