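#' @title Envelope preprocessing
#'
#' @description
#' Transforms raw sEMG into the bounded envelope inputs consumed by the
#' decoder network: full-wave rectification, a causal gain-free
#' moving-average FIR filter of length `W` samples, per-channel rescaling
#' by the 1st/99th calibration percentiles, clipping to `[0, 1]` and an
#' element-wise square root. Available in batch form (calibration) and as
#' an exactly equivalent sample-by-sample streaming filter (inference).
#' No time shift is introduced: envelope columns stay synchronous with the
#' raw recording (the FIR group delay is `(W - 1) / (2 Fs)` seconds).
#'
#' @name envelope_preprocessing
NULL

envelope_set <- function(values, stage, filter_length) {
  structure(list(values = values, stage = stage,
                 filter_length = as.integer(filter_length)),
            class = "envelope_set")
}

#' @export
print.envelope_set <- function(x, ...) {
  cat("<envelope_set>", nrow(x$values), "channels x", ncol(x$values),
      "samples, stage:", x$stage, ", W =", x$filter_length, "\n")
  invisible(x)
}

#' Extract raw (unbounded) sEMG envelopes
#'
#' Causal moving average of the rectified signal. During warm-up
#' (`t < W`) the mean is taken over the `t` samples available so far
#' (growing window), keeping the filter causal without a startup transient
#' of zeros.
#'
#' @param raw an [emg_recording].
#' @param window_seconds filter length in seconds (default 0.5 s, i.e.
#'   `W = 100` samples at 200 Hz).
#' @return An `envelope_set` (stage `"raw"`) with nonnegative values and
#'   the same number of samples as `raw`.
#' @export
extract_envelope <- function(raw, window_seconds = 0.5) {
  if (!inherits(raw, "emg_recording")) stop("raw must be an emg_recording")
  if (raw$n_samples < 1) stop("invalid input: empty recording")
  W <- as.integer(round(window_seconds * raw$sampling_rate))
  if (W < 1) stop("window_seconds too short: filter length must be >= 1 sample")
  x <- abs(raw$values)
  T_ <- ncol(x)
  env <- matrix(0, nrow(x), T_)
  denom <- c(seq_len(min(W, T_)), rep(W, max(0, T_ - W)))
  for (i in seq_len(nrow(x))) {
    cs <- .cumsum_dbl_cpp(x[i, ])
    lag <- c(rep(0, min(W, T_)), cs[seq_len(max(0, T_ - W))])
    env[i, ] <- (cs - lag) / denom
  }
  envelope_set(env, "raw", W)
}

#' Fit per-channel normalization statistics
#'
#' Computes the 1st and 99th percentile of every channel's raw envelope
#' across all samples (linear interpolation between order statistics).
#'
#' @param env an `envelope_set` of stage `"raw"`.
#' @return Object of class `normalization_stats` with vectors `p1`, `p99`.
#' @export
fit_normalization <- function(env) {
  if (!inherits(env, "envelope_set") || env$stage != "raw") {
    stop("env must be a raw-stage envelope_set")
  }
  if (ncol(env$values) < 100) stop("need at least 100 samples to fit percentiles")
  p1 <- apply(env$values, 1, stats::quantile, probs = 0.01, names = FALSE)
  p99 <- apply(env$values, 1, stats::quantile, probs = 0.99, names = FALSE)
  bad <- which(p99 <= p1)
  if (length(bad)) {
    stop("degenerate channel(s) ", paste(bad, collapse = ", "),
         ": 99th percentile does not exceed 1st percentile")
  }
  structure(list(p1 = p1, p99 = p99, n_channels = length(p1)),
            class = "normalization_stats")
}

#' Rescale, clip and square-root envelopes
#'
#' Applies the calibration statistics: per channel `i`,
#' `e <- sqrt(max(0, min(1, (E - p1_i) / (p99_i - p1_i))))`, producing the
#' bounded network inputs. Values at or below the 1st percentile map to 0
#' (an implicit rest threshold); the square root biases resolution towards
#' high contraction levels.
#'
#' @param env `envelope_set` of stage `"raw"`.
#' @param stats a `normalization_stats` fitted with [fit_normalization()].
#' @return An `envelope_set` of stage `"calibrated"` with values in `[0, 1]`.
#' @export
apply_normalization <- function(env, stats) {
  if (!inherits(stats, "normalization_stats")) stop("stats must be normalization_stats")
  if (nrow(env$values) != stats$n_channels) {
    stop("shape error: envelope has ", nrow(env$values),
         " channels but stats were fitted on ", stats$n_channels)
  }
  r <- (env$values - stats$p1) / (stats$p99 - stats$p1)
  envelope_set(sqrt(pmin(pmax(r, 0), 1)), "calibrated", env$filter_length)
}

#' Initialize a streaming envelope filter
#'
#' Creates mutable streaming state (reference semantics) replicating the
#' batch pipeline one sample at a time: rectification, causal moving
#' average with growing-window warm-up, then rescaling with the fitted
#' calibration statistics. Feeding a recording through
#' [envelope_stream_step()] reproduces the batch output bit for bit.
#'
#' @param stats `normalization_stats` from calibration.
#' @param filter_length FIR length `W` in samples.
#' @return An object of class `envelope_stream` (an environment).
#' @export
envelope_stream <- function(stats, filter_length = 100L) {
  if (!inherits(stats, "normalization_stats")) stop("state error: stats required")
  st <- new.env(parent = emptyenv())
  st$W <- as.integer(filter_length)
  st$I <- stats$n_channels
  st$p1 <- stats$p1
  st$scale <- stats$p99 - stats$p1
  st$csum <- numeric(stats$n_channels)          # running cumulative sums
  st$ring <- matrix(0, stats$n_channels, st$W)  # last W cumulative sums
  st$t <- 0L
  class(st) <- "envelope_stream"
  st
}

#' Advance the streaming envelope filter by one sample
#'
#' @param state an [envelope_stream()] object (mutated in place).
#' @param sample length-I raw voltage vector at the current time step.
#' @return The calibrated envelope vector in `[0, 1]^I` for this step.
#' @export
envelope_stream_step <- function(state, sample) {
  if (!inherits(state, "envelope_stream")) stop("state error: uninitialized stream")
  if (length(sample) != state$I) stop("shape error: expected ", state$I, " channels")
  t <- state$t + 1L
  cs <- state$csum + abs(sample)
  slot <- ((t - 1L) %% state$W) + 1L
  if (t <= state$W) {
    e <- cs / t
  } else {
    e <- (cs - state$ring[, slot]) / state$W
  }
  state$ring[, slot] <- cs
  state$csum <- cs
  state$t <- t
  r <- (e - state$p1) / state$scale
  sqrt(pmax(0, pmin(1, r)))
}

#' Full batch preprocessing pipeline
#'
#' Convenience wrapper: extract envelopes, fit (or reuse) normalization
#' statistics and apply them.
#'
#' @param raw an [emg_recording].
#' @param window_seconds FIR length in seconds.
#' @param stats optional pre-fitted `normalization_stats` (inference mode);
#'   fitted from `raw` when `NULL` (calibration mode).
#' @return List with `envelopes` (calibrated `envelope_set`) and `stats`.
#' @export
preprocess_emg <- function(raw, window_seconds = 0.5, stats = NULL) {
  eu <- extract_envelope(raw, window_seconds)
  if (is.null(stats)) stats <- fit_normalization(eu)
  list(envelopes = apply_normalization(eu, stats), stats = stats)
}
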