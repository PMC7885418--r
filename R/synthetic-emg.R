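#' @title Synthetic surface EMG
#'
#' @description
#' A phenomenological generator for multichannel surface EMG (sEMG):
#' amplitude-modulated white Gaussian noise, quantized to the 8-bit grid of
#' a wearable acquisition front end sampling at 200 Hz. Each simulated
#' subject has a distinct, nonnegative channel-gain pattern per movement
#' direction (wrist flexion/extension, digit flexion/extension), emulating
#' muscles lying under different electrodes of a circular forearm armband.
#' The generator produces both scripted calibration sessions (categorical
#' movement prompts with trapezoidal latent-intent ramps) and per-sample
#' continuous-intent EMG for closed-loop simulation.
#'
#' @name synthetic_emg
NULL

DIRECTION_NAMES <- c("wrist_flexion", "wrist_extension",
                     "digit_flexion", "digit_extension")

#' Create a simulated subject profile
#'
#' Draws a subject-specific channel-gain matrix: each of the four movement
#' directions has a preferred angular position on the circular electrode
#' array (antagonist directions on opposite sides), realized as a von
#' Mises-like tuning bump over channels with per-subject jitter. All gains
#' are nonnegative and every direction excites at least one channel.
#'
#' @param seed integer seed; the profile is a deterministic function of it.
#' @param n_channels number of sEMG channels (default 8).
#' @param baseline_noise_sd standing (rest) noise amplitude, in the
#'   arbitrary voltage units of the generator.
#' @param mvc_amplitude amplitude scale of a maximum voluntary contraction.
#' @param tuning_kappa concentration of the angular tuning bump.
#' @return An object of class `subject_profile` with fields `gains`
#'   (`n_channels` x 4 matrix, columns ordered wrist flexion, wrist
#'   extension, digit flexion, digit extension), `baseline_noise_sd`,
#'   `mvc_amplitude`, `v_range` (ADC full-scale voltage, set to 4x the
#'   largest expected signal amplitude so MVC never clips), `seed`.
#' @examples
#' p <- make_subject_profile(seed = 1)
#' dim(p$gains)
#' @export
make_subject_profile <- function(seed, n_channels = 8,
                                 baseline_noise_sd = 0.05,
                                 mvc_amplitude = 1.0,
                                 tuning_kappa = 2.5) {
  if (n_channels < 2) stop("invalid configuration: n_channels must be >= 2")
  if (baseline_noise_sd < 0 || mvc_amplitude <= 0) {
    stop("invalid configuration: amplitudes must be positive")
  }
  set.seed(seed)
  theta <- 2 * pi * (seq_len(n_channels) - 1) / n_channels
  # antagonists face opposite sides of the armband; digit DoF offset by 90 deg
  phi <- c(0, pi, pi / 2, 3 * pi / 2) + stats::rnorm(4, 0, 10 * pi / 180)
  gains <- sapply(phi, function(p) exp(tuning_kappa * (cos(theta - p) - 1)))
  gains <- gains * matrix(exp(stats::rnorm(n_channels * 4, 0, 0.15)),
                          n_channels, 4)
  # per-direction MVC strength jitter
  gains <- sweep(gains, 2, stats::runif(4, 0.9, 1.1), `*`)
  colnames(gains) <- DIRECTION_NAMES
  # ADC headroom: 4x the largest amplitude reachable at full compound intent
  worst <- max(vapply(list(c(1, 3), c(1, 4), c(2, 3), c(2, 4)),
                      function(dd) max(rowSums(gains[, dd, drop = FALSE])),
                      numeric(1)))
  v_range <- 4 * (baseline_noise_sd + mvc_amplitude * worst)
  structure(
    list(n_channels = n_channels, gains = gains,
         baseline_noise_sd = baseline_noise_sd,
         mvc_amplitude = mvc_amplitude,
         v_range = v_range, seed = seed),
    class = "subject_profile"
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat("<subject_profile> seed", x$seed, "-", x$n_channels, "channels,",
      "baseline sd", x$baseline_noise_sd, ", MVC amplitude",
      x$mvc_amplitude, "\n")
  invisible(x)
}

#' Acquisition protocol for scripted calibration sessions
#'
#' Defaults mirror a prompted protocol in which every non-rest movement is
#' performed for 3 repetitions of 5 s at 50% of the movement-specific MVC,
#' each preceded by 3 s of rest, sampled at 200 Hz with 8-bit quantization.
#'
#' @param movements ordered vector of non-rest class ids to prompt.
#' @param repetitions repetitions per movement.
#' @param movement_duration seconds of each instructed contraction.
#' @param rest_duration seconds of rest before each contraction.
#' @param contraction_level instructed intensity as a fraction of MVC.
#' @param sampling_rate Hz.
#' @param quantization_bits ADC resolution.
#' @param ramp_time seconds over which the latent intent ramps up at
#'   movement onset and down before offset (trapezoidal profile).
#' @param leading_rest include the rest period before the very first
#'   prompt? (Dropping it removes one `rest_duration` from the session.)
#' @return An object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(movements = 1:8, repetitions = 3,
                                 movement_duration = 5, rest_duration = 3,
                                 contraction_level = 0.5,
                                 sampling_rate = 200, quantization_bits = 8,
                                 ramp_time = 0.4, leading_rest = TRUE) {
  if (movement_duration <= 0 || rest_duration <= 0) {
    stop("invalid configuration: durations must be positive")
  }
  if (contraction_level <= 0 || contraction_level > 1) {
    stop("invalid configuration: contraction_level must lie in (0, 1]")
  }
  if (!all(movements %in% 1:8)) stop("movements must be non-rest class ids 1..8")
  structure(
    list(movements = as.integer(movements), repetitions = as.integer(repetitions),
         movement_duration = movement_duration, rest_duration = rest_duration,
         contraction_level = contraction_level, sampling_rate = sampling_rate,
         quantization_bits = as.integer(quantization_bits),
         ramp_time = ramp_time, leading_rest = isTRUE(leading_rest)),
    class = "acquisition_protocol"
  )
}

#' Raw EMG recording container
#'
#' @param values I x T numeric matrix of channel voltages.
#' @param sampling_rate Hz.
#' @param bits ADC resolution used to quantize `values`.
#' @param v_range ADC full-scale voltage (grid spans `[-v_range, v_range)`).
#' @return Object of class `emg_recording`.
#' @export
emg_recording <- function(values, sampling_rate, bits = 8L, v_range = NA_real_) {
  values <- as.matrix(values)
  structure(list(values = values, sampling_rate = sampling_rate,
                 bits = as.integer(bits), v_range = v_range,
                 n_channels = nrow(values), n_samples = ncol(values)),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat("<emg_recording>", x$n_channels, "channels x", x$n_samples,
      "samples @", x$sampling_rate, "Hz\n")
  invisible(x)
}

#' Stimulus (movement instruction) encoding container
#'
#' @param values J x T matrix with ternary entries in \{-1, 0, 1\}.
#' @return Object of class `stimulus_encoding`.
#' @export
stimulus_encoding <- function(values) {
  values <- as.matrix(values)
  if (!all(values %in% c(-1, 0, 1))) stop("stimulus entries must be ternary")
  structure(list(values = values, n_dofs = nrow(values),
                 n_samples = ncol(values)),
            class = "stimulus_encoding")
}

# per-channel signal amplitude implied by a (possibly compound) intent;
# intent columns are J = 2 vectors in [-1, 1]^2
intent_amplitude <- function(profile, intent) {
  intent <- as.matrix(intent)
  if (nrow(intent) != 2L) stop("intent must have 2 DoF rows")
  dirmag <- rbind(pmax(-intent[1L, ], 0), pmax(intent[1L, ], 0),
                  pmax(-intent[2L, ], 0), pmax(intent[2L, ], 0))
  profile$baseline_noise_sd +
    profile$mvc_amplitude * (profile$gains %*% dirmag)
}

# quantize to the signed 2^bits-level ADC grid covering [-v_range, v_range)
quantize_adc <- function(x, v_range, bits) {
  delta <- 2 * v_range / 2^bits
  lo <- -2^(bits - 1)
  hi <- 2^(bits - 1) - 1
  pmin(pmax(round(x / delta), lo), hi) * delta
}

#' Draw raw sEMG samples for a continuous movement intent
#'
#' The generator model is zero-mean white Gaussian noise whose per-channel
#' standard deviation is an affine function of the rectified intent:
#' `a_i = baseline + mvc * sum_d gains[i, d] * |intent_d|` over the active
#' directions, followed by 8-bit ADC quantization. Uses the R session RNG;
#' call `set.seed()` for reproducibility.
#'
#' @param profile a [make_subject_profile()] object.
#' @param intent length-2 vector in `[-1, 1]^2` (wrist, digits).
#' @param n number of consecutive samples to draw.
#' @return If `n == 1` a length-I voltage vector, else an I x n matrix.
#' @export
emg_sample <- function(profile, intent, n = 1) {
  if (any(abs(intent) > 1)) stop("intent components must lie in [-1, 1]")
  q <- .emg_draw_cpp(profile$gains, profile$baseline_noise_sd,
                     profile$mvc_amplitude, profile$v_range, 8L,
                     as.numeric(intent), as.integer(n))
  if (n == 1) as.numeric(q) else q
}

# build the latent intent (2 x T) and stimulus (2 x T) timelines of a session
session_timelines <- function(protocol) {
  fs <- protocol$sampling_rate
  n_move <- round(protocol$movement_duration * fs)
  n_rest <- round(protocol$rest_duration * fs)
  n_ramp <- round(protocol$ramp_time * fs)
  # trapezoid over one movement segment
  ramp <- if (n_ramp > 0) seq_len(n_ramp) / n_ramp else numeric(0)
  trap <- c(ramp, rep(1, max(0, n_move - 2 * n_ramp)), rev(ramp))[seq_len(n_move)]
  intent <- NULL; stim <- NULL
  first <- TRUE
  for (m in protocol$movements) {
    enc <- movement_encoding(m)
    for (r in seq_len(protocol$repetitions)) {
      if (!first || protocol$leading_rest) {
        intent <- cbind(intent, matrix(0, 2, n_rest))
        stim <- cbind(stim, matrix(0, 2, n_rest))
      }
      first <- FALSE
      intent <- cbind(intent, outer(enc * protocol$contraction_level, trap))
      stim <- cbind(stim, matrix(enc, 2, n_move))
    }
  }
  list(intent = intent, stimulus = stim)
}

#' Generate a full scripted calibration session
#'
#' Produces a raw recording and the synchronized ternary stimulus matrix.
#' Prompts follow block order (all repetitions of movement 1, then movement
#' 2, ...), each repetition preceded by a rest period. The stimulus holds
#' the exact ternary class encoding for the whole instructed segment while
#' the latent intent driving the EMG amplitude ramps trapezoidally, so that
#' (as with human subjects) signal onset does not align perfectly with the
#' categorical label.
#'
#' @param profile subject profile.
#' @param protocol acquisition protocol.
#' @param seed optional integer; when given, output is a deterministic
#'   function of `(profile, protocol, seed)`.
#' @return List with elements `recording` ([emg_recording]), `stimulus`
#'   ([stimulus_encoding]) and `intent` (the latent 2 x T intensity
#'   timeline, useful as ground truth in tests).
#' @export
generate_calibration_session <- function(profile, protocol = acquisition_protocol(),
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tl <- session_timelines(protocol)
  a <- intent_amplitude(profile, tl$intent)
  x <- a * matrix(stats::rnorm(length(a)), nrow(a), ncol(a))
  x <- quantize_adc(x, profile$v_range, protocol$quantization_bits)
  list(recording = emg_recording(x, protocol$sampling_rate,
                                 protocol$quantization_bits, profile$v_range),
       stimulus = stimulus_encoding(tl$stimulus),
       intent = tl$intent)
}

#' Generate per-movement maximum-voluntary-contraction recordings
#'
#' One recording per non-rest movement class, held at full intent
#' (magnitude 1) for `duration` seconds. Used to derive the
#' movement-specific MVC magnitudes that anchor the instructed 50%
#' contraction level.
#'
#' @param profile subject profile.
#' @param seed optional integer seed.
#' @param duration seconds (default 5).
#' @param sampling_rate Hz.
#' @return Named list of 8 [emg_recording] objects (`m1` ... `m8`).
#' @export
generate_mvc_recordings <- function(profile, seed = NULL, duration = 5,
                                    sampling_rate = 200) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * sampling_rate)
  out <- lapply(1:8, function(m) {
    x <- emg_sample(profile, movement_encoding(m), n = n)
    emg_recording(x, sampling_rate, 8L, profile$v_range)
  })
  names(out) <- paste0("m", 1:8)
  out
}
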