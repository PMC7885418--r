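# Shared fixtures: all synthetic, generated at test time.

# small, fast network for oracle comparisons
tiny_topology <- function(I = 3, J = 2) {
  mrl_topology(n_inputs = I, n_dofs = J, first_layer_log2 = 3,
               encoder_depth = 2, decoder_hidden_log2 = 2)
}

# random parameters with nonzero biases so every code path is exercised
tiny_params <- function(seed = 7, I = 3, J = 2) {
  params <- mrl_build(tiny_topology(I, J), seed = seed)
  set.seed(seed + 100)
  for (l in seq_along(params$encoder)) {
    params$encoder[[l]]$b <- stats::rnorm(length(params$encoder[[l]]$b), 0, 0.1)
  }
  for (j in seq_along(params$decoder)) {
    params$decoder[[j]]$hidden$b <- stats::rnorm(length(params$decoder[[j]]$hidden$b), 0, 0.1)
    params$decoder[[j]]$out$b <- stats::rnorm(1, 0, 0.1)
  }
  params
}

# all-zero parameters of the same topology
zero_params <- function(topology) {
  params <- mrl_build(topology, seed = 1)
  for (l in seq_along(params$encoder)) params$encoder[[l]]$W[] <- 0
  for (j in seq_along(params$decoder)) {
    params$decoder[[j]]$hidden$W[] <- 0
    params$decoder[[j]]$out$W[] <- 0
  }
  params
}

# a short synthetic calibration session (1 repetition, shortened segments)
quick_session <- function(seed = 1, ...) {
  prof <- make_subject_profile(seed = seed)
  proto <- acquisition_protocol(repetitions = 1, movement_duration = 2,
                                rest_duration = 1, ...)
  ses <- generate_calibration_session(prof, proto, seed = seed + 500)
  c(list(profile = prof, protocol = proto), ses)
}

# construct a trial_log directly (for metric tests)
fake_log <- function(distance = 300, radius = 60, outcome = "success",
                     ct = 2, overshoots = 0, path_length = NULL) {
  target <- data.frame(x = distance, y = 0, radius = radius,
                       distance = distance, diameter = 2 * radius,
                       id_bits = index_of_difficulty(distance, 2 * radius))
  if (is.null(path_length)) path_length <- distance
  structure(list(target = target, outcome = outcome,
                 completion_time = if (outcome == "success") ct else NA_real_,
                 overshoots = overshoots,
                 trajectory = matrix(c(0, 0), 1, 2),
                 path_length = path_length),
            class = "trial_log")
}

# central finite-difference gradient of a scalar function of one parameter
fd_grad <- function(fn, x, h = 1e-5) {
  g <- x
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    g[k] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  g
}
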