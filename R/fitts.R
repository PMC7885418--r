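#' @title Closed-loop Fitts's-law evaluation
#'
#' @description
#' Simulates the virtual target-acquisition test used to score myoelectric
#' controllers: 40 circular targets (20 centers, none on a coordinate
#' axis, times 2 radii) are presented one at a time; a scripted simulated
#' user produces a movement intent aimed at the target, the synthetic EMG
#' generator turns that intent into sEMG, the controller under test maps
#' sEMG to a cursor velocity, and a dwell/timeout state machine scores the
#' trial. Success requires 0.3 s (60 samples at 200 Hz) of uninterrupted
#' in-target residence; trials fail after 20 s.
#'
#' @name fitts_environment
NULL

#' Construct the 40-target layout
#'
#' Five center angles per quadrant (none axis-aligned) at three distances
#' cycled across angles (with a per-quadrant offset for balance), crossed
#' with two radii. The distance/diameter combinations yield 6 distinct
#' index-of-difficulty values. Default distances 213/350/505 px with radii
#' 60/85 px give IDs from 1.17 to 2.38 bits.
#'
#' @param distances three center distances from the origin, in pixels.
#' @param radii two target radii in pixels.
#' @param angles_deg five within-quadrant angles (degrees, strictly
#'   between 0 and 90).
#' @return A data.frame of 40 targets: `x`, `y`, `radius`, `distance`,
#'   `diameter`, `id_bits`.
#' @export
make_target_set <- function(distances = c(213, 350, 505), radii = c(60, 85),
                            angles_deg = c(15, 30, 45, 60, 75)) {
  if (length(angles_deg) != 5) stop("layout error: need 5 angles per quadrant")
  if (any(angles_deg %% 90 == 0)) stop("layout error: no target may lie on an axis")
  if (length(distances) != 3 || length(radii) != 2) {
    stop("layout error: need 3 distances and 2 radii")
  }
  rows <- list()
  for (q in 0:3) {
    for (a in seq_along(angles_deg)) {
      ang <- (q * 90 + angles_deg[a]) * pi / 180
      D <- distances[((a - 1 + q) %% 3) + 1]
      for (r in radii) {
        rows[[length(rows) + 1]] <- data.frame(
          x = D * cos(ang), y = D * sin(ang), radius = r,
          distance = D, diameter = 2 * r,
          id_bits = index_of_difficulty(D, 2 * r))
      }
    }
  }
  do.call(rbind, rows)
}

#' Cursor velocity of the representation-learning controller
#'
#' The two DoF estimates map linearly to screen velocity: a unit-norm
#' output corresponds to a speed of 540 px/s (wrist DoF drives x, digit
#' DoF drives y; positive values move right/up).
#'
#' @param yhat length-2 network output.
#' @param px_per_unit speed scale (px/s at unit output norm).
#' @return Length-2 velocity `(vx, vy)` in px/s.
#' @export
mrl_velocity <- function(yhat, px_per_unit = 540) px_per_unit * as.numeric(yhat)

#' Cursor velocity of the LDA benchmark controller
#'
#' The detected class fixes the direction (axis for 1-DoF classes,
#' diagonal for compound classes, per the ternary encoding); the
#' proportionality scalar fixes the speed: `PC_m = 1` gives 540 px/s,
#' scaled linearly without saturation. Rest gives zero velocity.
#'
#' @param m detected class id (0..8).
#' @param pc proportionality scalar `PC_m` (ignored for rest).
#' @param px_per_unit speed scale.
#' @return Length-2 velocity in px/s.
#' @export
lda_velocity <- function(m, pc, px_per_unit = 540) {
  if (m == 0) return(c(0, 0))
  enc <- movement_encoding(m)
  (enc / sqrt(sum(enc^2))) * px_per_unit * pc
}

#' Scripted simulated user
#'
#' A stand-in for the human operator: its intent points from the cursor
#' towards the target center with magnitude ramping down within
#' `slow_radius` px of the center (zero at the center), perturbed by
#' Gaussian direction and magnitude noise and smoothed by a first-order
#' reaction lag. Real users differ in strategy, learning and tremor; this
#' model only reproduces noisy goal-directed aiming.
#'
#' @param direction_noise_sd SD of the aiming-angle perturbation (radians).
#' @param magnitude_noise_sd SD of the intent-magnitude perturbation.
#' @param max_intent peak commanded intent magnitude (<= 1).
#' @param slow_radius distance (px) under which intent ramps down linearly.
#' @param reaction_tau first-order intent smoothing time constant (s).
#' @param lead_time anticipation horizon (s): the user aims from the
#'   cursor position extrapolated by `lead_time` at its current velocity,
#'   emulating the predictive braking human operators use to compensate
#'   the envelope-filter group delay (about 0.25 s at the default filter).
#' @return Object of class `simulated_user`.
#' @export
simulated_user <- function(direction_noise_sd = 0.15, magnitude_noise_sd = 0.05,
                           max_intent = 0.8, slow_radius = 200,
                           reaction_tau = 0.1, lead_time = 0.25) {
  structure(list(direction_noise_sd = direction_noise_sd,
                 magnitude_noise_sd = magnitude_noise_sd,
                 max_intent = max_intent, slow_radius = slow_radius,
                 reaction_tau = reaction_tau, lead_time = lead_time),
            class = "simulated_user")
}

# raw (pre-smoothing) intent of the simulated user
user_intent_raw <- function(user, cursor, target_xy) {
  v <- target_xy - cursor
  dist <- sqrt(sum(v * v))
  if (dist < 1e-9) return(c(0, 0))
  ang <- atan2(v[2], v[1]) + stats::rnorm(1, 0, user$direction_noise_sd)
  mag <- user$max_intent * min(1, dist / user$slow_radius) +
    stats::rnorm(1, 0, user$magnitude_noise_sd)
  mag <- min(max(mag, 0), user$max_intent)
  mag * c(cos(ang), sin(ang))
}

#' Run one target-acquisition trial
#'
#' The cursor is frozen at the origin for `hold_seconds` (rest EMG keeps
#' flowing, so streaming filter states evolve realistically), after which
#' control is granted and the clock starts. Each 1/rate step: the user
#' emits an intent, the subject profile turns it into an sEMG sample, the
#' controller maps that to a velocity, and the cursor integrates it.
#' Success occurs at the first instant the cursor has been strictly inside
#' the target boundary for `dwell_seconds` consecutively; every exit from
#' the boundary before dwell completion counts one overshoot. Failure is
#' declared after `timeout` seconds of control.
#'
#' @param controller a controller object (see [mrl_controller()],
#'   [lda_controller()], [scripted_controller()]).
#' @param target one-row data.frame from [make_target_set()].
#' @param user a [simulated_user()].
#' @param profile subject profile generating the sEMG.
#' @param timeout,hold_seconds,dwell_seconds,rate trial state-machine
#'   constants (20 s, 3 s, 0.3 s, 200 Hz).
#' @return Object of class `trial_log`: `target`, `outcome`
#'   (`"success"`/`"failure"`), `completion_time` (s, NA on failure),
#'   `overshoots`, `trajectory` (n x 2 matrix from control grant on,
#'   starting at the origin), `path_length`.
#' @export
run_trial <- function(controller, target, user, profile, timeout = 20,
                      hold_seconds = 3, dwell_seconds = 0.3, rate = 200) {
  dt <- 1 / rate
  dwell_n <- round(dwell_seconds * rate)
  tgt <- c(target$x, target$y)
  # hold phase: rest EMG, cursor pinned at origin (filters keep running)
  for (k in seq_len(round(hold_seconds * rate))) {
    controller$idle(emg_sample(profile, c(0, 0)))
  }
  cursor <- c(0, 0)
  n_max <- round(timeout * rate)
  traj <- matrix(NA_real_, n_max + 1L, 2L)
  traj[1L, ] <- cursor
  intent <- c(0, 0)
  cursor_prev <- cursor
  inside_prev <- FALSE
  dwell_cnt <- 0L
  overshoots <- 0L
  outcome <- "failure"
  ct <- NA_real_
  n_used <- 0L
  for (k in seq_len(n_max)) {
    predicted <- cursor + user$lead_time * (cursor - cursor_prev) / dt
    raw <- user_intent_raw(user, predicted, tgt)
    a <- min(1, dt / user$reaction_tau)
    intent <- intent + a * (raw - intent)
    intent <- pmin(pmax(intent, -1), 1)
    v <- controller$step(emg_sample(profile, intent), cursor, k * dt)
    cursor_prev <- cursor
    cursor <- cursor + v * dt
    traj[k + 1L, ] <- cursor
    n_used <- k
    inside <- sum((cursor - tgt)^2) < target$radius^2
    if (inside) {
      dwell_cnt <- dwell_cnt + 1L
      if (dwell_cnt >= dwell_n) {
        outcome <- "success"
        ct <- k * dt
        break
      }
    } else {
      if (inside_prev) overshoots <- overshoots + 1L
      dwell_cnt <- 0L
    }
    inside_prev <- inside
  }
  traj <- traj[seq_len(n_used + 1L), , drop = FALSE]
  steps <- diff(traj)
  structure(list(target = target, outcome = outcome, completion_time = ct,
                 overshoots = overshoots, trajectory = traj,
                 path_length = sum(sqrt(rowSums(steps^2)))),
            class = "trial_log")
}

#' Run a full 40-target session
#'
#' Presents every target exactly once in a randomized order, with 5 s of
#' simulated rest (zero intent, EMG still flowing through the controller's
#' filters) between trials.
#'
#' @param controller controller object (its internal filter state persists
#'   across the session).
#' @param targets 40-row data.frame from [make_target_set()].
#' @param user a [simulated_user()].
#' @param profile subject profile.
#' @param seed optional seed fixing target order, user noise and EMG draws.
#' @param rest_seconds inter-trial rest duration.
#' @param ... passed to [run_trial()].
#' @return List of `trial_log`s, one per target, in presentation order.
#' @export
run_session <- function(controller, targets, user, profile, seed = NULL,
                        rest_seconds = 5, ...) {
  if (!is.null(seed)) set.seed(seed)
  order_ <- sample.int(nrow(targets))
  logs <- vector("list", nrow(targets))
  for (k in seq_along(order_)) {
    if (k > 1) {
      for (s in seq_len(round(rest_seconds * 200))) {
        controller$idle(emg_sample(profile, c(0, 0)))
      }
    }
    logs[[k]] <- run_trial(controller, targets[order_[k], , drop = FALSE],
                           user, profile, ...)
  }
  logs
}

#' Representation-learning controller
#'
#' Wraps a calibrated network and its preprocessing statistics into a
#' stateful per-sample controller: streaming envelope extraction and
#' normalization, a network forward pass, and the linear velocity map.
#'
#' @param params calibrated `mrl_parameters` (or an `mrl_fit`).
#' @param stats `normalization_stats` fitted on the calibration data.
#' @param filter_length envelope FIR length in samples.
#' @param px_per_unit speed scale (px/s at unit output norm).
#' @return Controller object with a `$step(sample, cursor, t)` method
#'   returning a velocity, and `$reset()`.
#' @export
mrl_controller <- function(params, stats, filter_length = 100L,
                           px_per_unit = 540) {
  if (inherits(params, "mrl_fit")) params <- params$params
  stream <- envelope_stream(stats, filter_length)
  list(
    step = function(sample, cursor, t) {
      e <- envelope_stream_step(stream, sample)
      yhat <- .mrl_forward_vec_cpp(params$encoder, params$decoder, e,
                                   params$topology$activation_slope,
                                   params$topology$layernorm_eps)
      mrl_velocity(yhat, px_per_unit)
    },
    idle = function(sample) {
      envelope_stream_step(stream, sample)
      invisible(NULL)
    },
    reset = function() stream <<- envelope_stream(stats, filter_length),
    kind = "mrl"
  )
}

#' LDA benchmark controller
#'
#' Maintains the trailing raw-sample window, recomputed every sample so
#' that both controllers update at the EMG rate; classifies it, computes
#' the proportionality scalar for non-rest classes and maps to velocity.
#' Emits zero velocity until one full window has been observed.
#'
#' @param model fitted `lda_model`.
#' @param window feature window length in samples.
#' @param px_per_unit speed scale.
#' @return Controller object (`$step`, `$reset`).
#' @export
lda_controller <- function(model, window = 32L, px_per_unit = 540) {
  I <- model$n_channels
  buf <- matrix(0, I, window)
  filled <- 0L
  pos <- 0L
  tab <- movement_classes()
  dirs <- rbind(tab$wrist, tab$digits)
  nrm <- sqrt(colSums(dirs^2)); nrm[nrm == 0] <- 1
  dirs <- sweep(dirs, 2, nrm, "/")
  list(
    step = function(sample, cursor, t) {
      pos <<- (pos %% window) + 1L
      buf[, pos] <<- sample
      filled <<- min(filled + 1L, window)
      if (filled < window) return(c(0, 0))
      .lda_vel_cpp(buf, pos, model$scaler$mean, model$scaler$sd,
                   model$discriminant$A, model$discriminant$c0,
                   model$tables$S, model$tables$C, dirs, px_per_unit)
    },
    idle = function(sample) {
      pos <<- (pos %% window) + 1L
      buf[, pos] <<- sample
      filled <<- min(filled + 1L, window)
      invisible(NULL)
    },
    reset = function() { buf[] <<- 0; filled <<- 0L; pos <<- 0L },
    kind = "lda"
  )
}

#' Scripted (open-loop) controller
#'
#' Ignores the EMG and returns `velocity_fn(t, cursor)`; used to test the
#' trial state machine with exactly known kinematics.
#'
#' @param velocity_fn function of `(t, cursor)` returning a velocity.
#' @return Controller object.
#' @export
scripted_controller <- function(velocity_fn) {
  list(step = function(sample, cursor, t) velocity_fn(t, cursor),
       idle = function(sample) invisible(NULL),
       reset = function() invisible(NULL),
       kind = "scripted")
}
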