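#' @title Model calibration
#'
#' @description
#' Calibrates the multitask network on preprocessed envelopes and ternary
#' stimulus labels by minimizing `L = L_i + alpha_c * L_c`, where `L_i` is
#' the mean per-sample L1 inference error and `L_c` the contractive
#' penalty (mean squared input-output Jacobian entry). Training inputs are
#' corrupted with isotropic Gaussian noise each iteration (denoising-style
#' augmentation), optimization uses AdamW minibatch updates, and early
#' stopping monitors a clean held-out validation loss with a lookback
#' horizon.
#'
#' @name mrl_calibration
NULL

#' Training configuration
#'
#' Defaults are the reference hyperparameter set of the framework:
#' contractive weight `1e-2`, Adam step `1e-4` with `beta1 = 0.9`,
#' `beta2 = 0.999`, decoupled weight decay `1e-6` (weights only), input
#' corruption variance `0.1`, minibatch size `4096`, 10% validation
#' hold-out, lookback 300 iterations, at most 5000 iterations. One
#' iteration is one minibatch update; membership is reshuffled every
#' epoch. Scale `batch_size` / `max_iterations` down for quick runs.
#'
#' @param contractive_weight weighting `alpha_c` of the contractive loss.
#' @param learning_rate AdamW step size `eta`.
#' @param beta1,beta2 AdamW moment decay rates.
#' @param weight_decay decoupled weight decay `lambda` (applied to weights,
#'   not biases).
#' @param noise_variance variance `sigma^2` of the additive Gaussian input
#'   corruption.
#' @param batch_size minibatch size `B`.
#' @param validation_fraction fraction `P` of samples held out.
#' @param lookback early-stopping horizon `V` in iterations.
#' @param max_iterations cap `M` on parameter updates.
#' @param seed RNG seed controlling split, shuffling, corruption and
#'   parameter initialization.
#' @param contractive_on_corrupted evaluate the Jacobian penalty at the
#'   corrupted training inputs (default) or at the clean ones.
#' @param validation_loss `"total"` (inference + weighted contractive, the
#'   default) or `"inference"` for the early-stopping criterion; whether
#'   the monitored loss includes the Jacobian penalty is a genuinely open
#'   choice, and `"inference"` is substantially cheaper.
#' @return Object of class `mrl_config`.
#' @export
mrl_config <- function(contractive_weight = 1e-2, learning_rate = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, weight_decay = 1e-6,
                       noise_variance = 1e-1, batch_size = 4096,
                       validation_fraction = 0.1, lookback = 300,
                       max_iterations = 5000, seed = 1L,
                       contractive_on_corrupted = TRUE,
                       validation_loss = c("total", "inference")) {
  validation_loss <- match.arg(validation_loss)
  stopifnot(contractive_weight >= 0, learning_rate > 0,
            batch_size >= 1, lookback >= 1, max_iterations >= 1,
            noise_variance >= 0,
            validation_fraction > 0, validation_fraction < 1)
  structure(as.list(environment()), class = "mrl_config")
}

#' Inference loss (DoF-wise mean absolute error)
#'
#' Mean over samples of the L1 norm of the per-sample target-output
#' difference.
#'
#' @param targets J x B matrix of ternary targets.
#' @param outputs J x B matrix of network outputs.
#' @return Scalar loss.
#' @export
inference_loss <- function(targets, outputs) {
  targets <- as.matrix(targets); outputs <- as.matrix(outputs)
  if (!all(dim(targets) == dim(outputs))) stop("shape mismatch between targets and outputs")
  sum(abs(targets - outputs)) / ncol(targets)
}

#' Contractive loss (mean squared Jacobian entry)
#'
#' Squared partial derivative of every output DoF with respect to every
#' input channel, evaluated at each provided sample and averaged over
#' samples, channels and DoFs (the mean squared Frobenius-norm
#' contribution of the network Jacobian).
#'
#' @param params an `mrl_parameters` object.
#' @param batch I x B matrix of envelope samples (or a length-I vector).
#' @return Scalar loss.
#' @export
contractive_loss <- function(params, batch) {
  if (!is.matrix(batch)) batch <- matrix(batch, ncol = 1)
  mrl_engine(params, batch, Y = NULL, alpha_c = 1,
             need_grad = FALSE, need_tangent = TRUE)$L_c
}

#' Combined calibration loss
#'
#' @param L_i inference loss.
#' @param L_c contractive loss.
#' @param alpha_c contractive weight.
#' @return `L_i + alpha_c * L_c`.
#' @export
total_loss <- function(L_i, L_c, alpha_c) L_i + alpha_c * L_c

#' Corrupt a batch with isotropic Gaussian noise
#'
#' Adds i.i.d. `N(0, noise_variance)` noise to every element; no clipping
#' is applied afterwards. Uses the session RNG.
#'
#' @param batch numeric matrix or vector.
#' @param noise_variance noise variance `sigma^2` (>= 0).
#' @return Corrupted batch of the same shape.
#' @export
corrupt <- function(batch, noise_variance) {
  if (noise_variance < 0) stop("noise_variance must be >= 0")
  if (noise_variance == 0) return(batch)
  batch + stats::rnorm(length(batch), sd = sqrt(noise_variance))
}

#' Split sample indices into training and validation sets
#'
#' Validation membership is sampled randomly without replacement;
#' `round(fraction * n)` samples are held out.
#'
#' @param n total number of samples.
#' @param fraction validation fraction `P` in (0, 1).
#' @return List with integer index vectors `train` and `validation`
#'   (disjoint, union = `1:n`).
#' @export
split_validation <- function(n, fraction) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  n_val <- round(fraction * n)
  if (n_val < 1 || n_val >= n) stop("configuration error: split produces an empty set")
  val <- sort(sample.int(n, n_val))
  list(train = setdiff(seq_len(n), val), validation = val)
}

# one AdamW step over the nested parameter/gradient structure
adamw_step <- function(params, grads, state, cfg, iter) {
  b1 <- cfg$beta1; b2 <- cfg$beta2; eta <- cfg$learning_rate
  c1 <- 1 - b1^iter; c2 <- 1 - b2^iter
  upd <- function(theta, g, m, v, decay) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    theta <- theta - eta * (m / c1) / (sqrt(v / c2) + 1e-8)
    if (decay) theta <- theta - eta * cfg$weight_decay * theta
    list(theta = theta, m = m, v = v)
  }
  walk <- function(layer, g, st) {
    rw <- upd(layer$W, g$W, st$W$m, st$W$v, decay = TRUE)
    rb <- upd(layer$b, as.numeric(g$b), st$b$m, st$b$v, decay = FALSE)
    list(layer = list(W = rw$theta, b = rb$theta),
         st = list(W = list(m = rw$m, v = rw$v), b = list(m = rb$m, v = rb$v)))
  }
  for (l in seq_along(params$encoder)) {
    r <- walk(params$encoder[[l]], grads$encoder[[l]], state$encoder[[l]])
    params$encoder[[l]] <- r$layer; state$encoder[[l]] <- r$st
  }
  for (j in seq_along(params$decoder)) {
    r <- walk(params$decoder[[j]]$hidden, grads$decoder[[j]]$hidden,
              state$decoder[[j]]$hidden)
    params$decoder[[j]]$hidden <- r$layer; state$decoder[[j]]$hidden <- r$st
    r <- walk(params$decoder[[j]]$out, grads$decoder[[j]]$out,
              state$decoder[[j]]$out)
    params$decoder[[j]]$out <- r$layer; state$decoder[[j]]$out <- r$st
  }
  list(params = params, state = state)
}

adamw_init <- function(params) {
  zl <- function(layer) list(W = list(m = layer$W * 0, v = layer$W * 0),
                             b = list(m = layer$b * 0, v = layer$b * 0))
  list(encoder = lapply(params$encoder, zl),
       decoder = lapply(params$decoder, function(d)
         list(hidden = zl(d$hidden), out = zl(d$out))))
}

#' Calibrate the network on envelope/stimulus data
#'
#' Runs minibatch AdamW on the combined loss. Each epoch reshuffles
#' minibatch membership; every training batch is corrupted with Gaussian
#' noise before loss evaluation (the Jacobian penalty is, by default,
#' evaluated at the corrupted inputs as well). After every update the full
#' loss is computed on the clean validation split; optimization stops when
#' the validation loss exceeds its value `lookback` iterations earlier, or
#' after `max_iterations` updates. The returned parameters are the
#' best-validation snapshot.
#'
#' @param envelopes calibrated `envelope_set` or I x T numeric matrix in
#'   `[0, 1]`.
#' @param stimuli `stimulus_encoding` or J x T ternary matrix, column-wise
#'   synchronous with `envelopes`.
#' @param topology an [mrl_topology()] (defaults to the reference
#'   8-channel, 2-DoF configuration).
#' @param config an [mrl_config()].
#' @return List of class `mrl_fit`: `params` (best-validation
#'   `mrl_parameters`), `log` (per-iteration data.frame with `L`, `L_i`,
#'   `L_c`, `L_v`), `stop_reason` (`"lookback"` or `"max-iter"`),
#'   `best_iteration`, `stats` slot (`NULL`; attach preprocessing stats
#'   for deployment).
#' @export
mrl_calibrate <- function(envelopes, stimuli, topology = mrl_topology(),
                          config = mrl_config()) {
  E <- if (inherits(envelopes, "envelope_set")) envelopes$values else as.matrix(envelopes)
  Y <- if (inherits(stimuli, "stimulus_encoding")) stimuli$values else as.matrix(stimuli)
  if (ncol(E) != ncol(Y)) stop("envelopes and stimuli must be column-synchronous")
  if (nrow(E) != topology$n_inputs || nrow(Y) != topology$n_dofs) {
    stop("shape error: data dimensions do not match the topology")
  }
  cfg <- config
  set.seed(cfg$seed)
  split <- split_validation(ncol(E), cfg$validation_fraction)
  Etr <- E[, split$train, drop = FALSE]; Ytr <- Y[, split$train, drop = FALSE]
  Eva <- E[, split$validation, drop = FALSE]; Yva <- Y[, split$validation, drop = FALSE]
  n_tr <- ncol(Etr)
  B <- min(cfg$batch_size, n_tr)

  params <- mrl_build(topology, seed = cfg$seed)
  set.seed(cfg$seed + 1L)
  opt <- adamw_init(params)
  ac <- cfg$contractive_weight
  need_tan <- ac > 0
  val_tan <- need_tan && identical(cfg$validation_loss, "total")

  log_L <- log_Li <- log_Lc <- log_Lv <- numeric(0)
  best_Lv <- Inf; best_params <- params; best_iter <- 0L
  stop_reason <- "max-iter"
  iter <- 0L; batch_order <- integer(0); pos <- 1L

  while (iter < cfg$max_iterations) {
    if (pos + B - 1L > length(batch_order)) {   # new epoch
      batch_order <- sample.int(n_tr)
      pos <- 1L
    }
    idx <- batch_order[pos:(pos + B - 1L)]
    pos <- pos + B
    iter <- iter + 1L

    Eb <- Etr[, idx, drop = FALSE]
    Ebc <- corrupt(Eb, cfg$noise_variance)
    if (cfg$contractive_on_corrupted || cfg$noise_variance == 0) {
      res <- mrl_engine(params, Ebc, Ytr[, idx, drop = FALSE], ac,
                        need_grad = TRUE, need_tangent = need_tan)
    } else {
      res <- mrl_engine(params, Ebc, Ytr[, idx, drop = FALSE], 0,
                        need_grad = TRUE, need_tangent = FALSE)
      resc <- mrl_engine(params, Eb, NULL, ac, need_grad = TRUE,
                         need_tangent = TRUE)
      res$grads <- add_grads(res$grads, resc$grads)
      res$L_c <- resc$L_c
      res$L <- res$L_i + ac * res$L_c
    }
    if (!is.finite(res$L)) {
      stop("training diverged: non-finite loss at iteration ", iter)
    }
    st <- adamw_step(params, res$grads, opt, cfg, iter)
    params <- st$params; opt <- st$state

    val <- mrl_engine(params, Eva, Yva, ac, need_grad = FALSE,
                      need_tangent = val_tan)
    Lv <- if (val_tan) val$L_i + ac * val$L_c else val$L_i
    log_L <- c(log_L, res$L); log_Li <- c(log_Li, res$L_i)
    log_Lc <- c(log_Lc, if (need_tan) res$L_c else 0)
    log_Lv <- c(log_Lv, Lv)
    if (Lv < best_Lv) { best_Lv <- Lv; best_params <- params; best_iter <- iter }
    if (iter > cfg$lookback && Lv > log_Lv[iter - cfg$lookback]) {
      stop_reason <- "lookback"
      break
    }
  }
  structure(list(params = best_params,
                 log = data.frame(iteration = seq_along(log_L), L = log_L,
                                  L_i = log_Li, L_c = log_Lc, L_v = log_Lv),
                 stop_reason = stop_reason, best_iteration = best_iter,
                 stats = NULL),
            class = "mrl_fit")
}

# elementwise sum of two gradient structures
add_grads <- function(a, b) {
  for (l in seq_along(a$encoder)) {
    a$encoder[[l]]$W <- a$encoder[[l]]$W + b$encoder[[l]]$W
    a$encoder[[l]]$b <- a$encoder[[l]]$b + b$encoder[[l]]$b
  }
  for (j in seq_along(a$decoder)) {
    for (part in c("hidden", "out")) {
      a$decoder[[j]][[part]]$W <- a$decoder[[j]][[part]]$W + b$decoder[[j]][[part]]$W
      a$decoder[[j]][[part]]$b <- a$decoder[[j]][[part]]$b + b$decoder[[j]][[part]]$b
    }
  }
  a
}

#' @export
print.mrl_fit <- function(x, ...) {
  cat("<mrl_fit>", nrow(x$log), "iterations, stopped on", x$stop_reason,
      "- best validation loss", format(min(x$log$L_v), digits = 4),
      "at iteration", x$best_iteration, "\n")
  invisible(x)
}
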