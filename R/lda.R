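#' @title Pattern-recognition benchmark (time-domain features + LDA)
#'
#' @description
#' The benchmark controller is motion-normalized proportional pattern
#' recognition: four Hudgins time-domain features per channel (mean
#' absolute value, zero crossings, slope sign changes, waveform length)
#' extracted from sliding 32-sample windows, a `3^J`-class linear
#' discriminant classifier on the z-scored features, and a class-specific
#' proportionality scalar computed from per-class mean calibration MAVs:
#' `PC_m = ((1/C_m) * sum_i S[i,m] * MAV_i)^2` with `C_m = sum_i S[i,m]`.
#'
#' @name lda_benchmark
NULL

#' Hudgins time-domain features of one window
#'
#' @param window numeric vector (one channel), length >= 2.
#' @param zc_threshold amplitude threshold for counting a zero crossing
#'   (default 0: every sign change counts).
#' @param ssc_threshold threshold for counting a slope sign change.
#' @return Named numeric vector `(mav, zc, ssc, wl)`: mean absolute value,
#'   zero-crossing count, slope-sign-change count, waveform length.
#' @examples
#' td_features(c(1, -1, 1, -1)) # mav 1, zc 3, wl 6
#' @export
td_features <- function(window, zc_threshold = 0, ssc_threshold = 0) {
  n <- length(window)
  if (n < 2) stop("window too short: need at least 2 samples")
  d <- diff(window)
  zc <- sum(window[-n] * window[-1] < 0 & abs(d) >= zc_threshold)
  ssc <- 0
  if (n >= 3) {
    a <- window[2:(n - 1)] - window[1:(n - 2)]
    b <- window[2:(n - 1)] - window[3:n]
    ssc <- sum(a * b > 0 & (abs(a) >= ssc_threshold | abs(b) >= ssc_threshold))
  }
  c(mav = mean(abs(window)), zc = zc, ssc = ssc, wl = sum(abs(d)))
}

#' Slide a feature window over a recording
#'
#' Extracts the 4 time-domain features from every channel over windows of
#' `window` samples advanced by `increment` samples, yielding
#' `floor((T - window) / increment) + 1` feature vectors of length `4 * I`.
#' When a stimulus is supplied, each window receives the movement class
#' label determined by majority vote over its constituent per-sample class
#' ids (ties break to the lowest class id).
#'
#' @param recording an [emg_recording].
#' @param stimulus optional [stimulus_encoding] synchronous with the
#'   recording.
#' @param window window length in samples (default 32, i.e. 160 ms at
#'   200 Hz).
#' @param increment window advance in samples (default 3, i.e. 15 ms).
#' @param zc_threshold,ssc_threshold thresholds passed to [td_features()].
#' @return List with `features` (n_windows x 4I matrix; columns grouped by
#'   channel as mav/zc/ssc/wl), `labels` (integer vector or NULL) and
#'   `window_start` (first sample index of each window).
#' @export
window_stream <- function(recording, stimulus = NULL, window = 32L,
                          increment = 3L, zc_threshold = 0, ssc_threshold = 0) {
  X <- recording$values
  T_ <- ncol(X); I <- nrow(X)
  if (T_ < window) stop("recording shorter than one feature window")
  starts <- seq(1L, T_ - window + 1L, by = increment)
  feats <- matrix(0, length(starts), 4L * I)
  colnames(feats) <- paste0(rep(c("mav", "zc", "ssc", "wl"), I), "_ch",
                            rep(seq_len(I), each = 4))
  for (w in seq_along(starts)) {
    seg <- X[, starts[w]:(starts[w] + window - 1L), drop = FALSE]
    feats[w, ] <- .td_features_all_cpp(seg, zc_threshold, ssc_threshold)
  }
  labels <- NULL
  if (!is.null(stimulus)) {
    cls <- encoding_to_class(stimulus$values)
    labels <- vapply(starts, function(s) {
      tab <- table(cls[s:(s + window - 1L)])
      cand <- as.integer(names(tab)[tab == max(tab)])
      min(cand)
    }, integer(1))
  }
  list(features = feats, labels = labels, window_start = starts)
}

#' Fit the LDA benchmark controller
#'
#' Z-scores all features with calibration moments, fits a Gaussian linear
#' discriminant (pooled within-class covariance, uniform priors) over the
#' `3^J = 9` movement classes, and tabulates the per-class mean
#' calibration MAVs `S[i, m]` (from the raw, unscaled MAV features) with
#' their column sums `C_m` used for proportional speed scaling.
#'
#' @param features n_windows x 4I calibration feature matrix from
#'   [window_stream()].
#' @param labels integer class labels (0..8) per window.
#' @param n_channels number of sEMG channels `I`.
#' @param ridge relative ridge added to the pooled covariance diagonal when
#'   it is numerically singular.
#' @return Object of class `lda_model` with the scaler, discriminant
#'   pieces and `tables` (list `S` I x M, `C` length M, `classes`).
#' @export
lda_fit <- function(features, labels, n_channels = 8, ridge = 1e-6) {
  classes <- sort(unique(labels))
  expected <- 0:8
  missing <- setdiff(expected, classes)
  if (length(missing)) {
    stop("calibration coverage error: no windows for class(es) ",
         paste(missing, collapse = ", "))
  }
  if (any(table(labels) < 2)) stop("every class needs at least 2 windows")
  mu <- colMeans(features)
  sdv <- apply(features, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(features, 2, mu), 2, sdv, "/")
  M <- length(expected)
  means <- t(vapply(expected, function(m) colMeans(Z[labels == m, , drop = FALSE]),
                    numeric(ncol(Z))))
  # pooled within-class covariance
  Sw <- matrix(0, ncol(Z), ncol(Z))
  for (m in expected) {
    Zm <- Z[labels == m, , drop = FALSE]
    Zc <- sweep(Zm, 2, colMeans(Zm))
    Sw <- Sw + crossprod(Zc)
  }
  Sw <- Sw / (nrow(Z) - M)
  inv <- tryCatch(solve(Sw), error = function(e) NULL)
  if (is.null(inv)) {
    Sw <- Sw + diag(ridge * sum(diag(Sw)) / ncol(Sw), ncol(Sw))
    inv <- solve(Sw)
  }
  # linear discriminant: delta_m(x) = x' inv mu_m - 0.5 mu_m' inv mu_m
  A <- inv %*% t(means)                        # p x M
  c0 <- -0.5 * colSums(t(means) * A)
  # proportionality tables from raw MAVs (every 4th column starting at 1)
  mav_cols <- seq(1L, by = 4L, length.out = n_channels)
  S <- vapply(expected, function(m)
    colMeans(features[labels == m, mav_cols, drop = FALSE]), numeric(n_channels))
  C <- colSums(S)
  structure(list(scaler = list(mean = mu, sd = sdv),
                 discriminant = list(A = A, c0 = c0),
                 classes = expected,
                 tables = list(S = S, C = C, classes = expected),
                 n_channels = n_channels),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat("<lda_model>", length(x$classes), "classes,",
      length(x$scaler$mean), "features,", x$n_channels, "channels\n")
  invisible(x)
}

#' Classify feature vectors
#'
#' Applies the calibration z-scoring and returns the class with the
#' largest linear discriminant score; ties break deterministically to the
#' lowest class index.
#'
#' @param model an `lda_model`.
#' @param features length-4I vector or n x 4I matrix of raw features.
#' @return Integer class id(s) in 0..8.
#' @export
lda_classify <- function(model, features) {
  if (!inherits(model, "lda_model")) stop("model must be a fitted lda_model")
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  Z <- sweep(sweep(X, 2, model$scaler$mean), 2, model$scaler$sd, "/")
  scores <- Z %*% model$discriminant$A +
    rep(model$discriminant$c0, each = nrow(Z))
  model$classes[apply(scores, 1, which.max)]
}

#' Motion-normalized proportionality scalar
#'
#' `PC_m = ((1/C_m) * sum_i S[i, m] * MAV_i)^2` for the detected non-rest
#' class `m`: the current channel MAVs projected onto the class's mean
#' calibration MAV pattern, normalized by the pattern sum and squared.
#' Not guaranteed to be <= 1 for contractions stronger than calibration.
#'
#' @param mav length-I vector of current (raw) channel MAVs.
#' @param m detected movement class (non-rest).
#' @param tables the `tables` element of a fitted `lda_model`.
#' @return Nonnegative scalar.
#' @export
lda_proportionality <- function(mav, m, tables) {
  k <- match(m, tables$classes)
  if (is.na(k) || m == 0) stop("m must be a valid non-rest class id")
  Cm <- tables$C[k]
  if (Cm <= 0) stop("degenerate class ", m, ": C_m is zero")
  (sum(tables$S[, k] * mav) / Cm)^2
}

#' Movement-specific MVC magnitude of a recording
#'
#' Maximum, over all positions of a sliding window (default 0.5 s), of the
#' channel-summed mean absolute value. Anchors the instructed contraction
#' level during calibration prompting.
#'
#' @param recording an [emg_recording].
#' @param window_seconds sliding window length in seconds.
#' @return Scalar magnitude.
#' @export
mvc_magnitude <- function(recording, window_seconds = 0.5) {
  W <- round(window_seconds * recording$sampling_rate)
  if (recording$n_samples < W) stop("recording too short for the MVC window")
  x <- abs(recording$values)
  T_ <- ncol(x)
  summed <- colSums(x)
  cs <- c(0, cumsum(summed))
  max((cs[(W + 1):(T_ + 1)] - cs[1:(T_ - W + 1)]) / W)
}
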