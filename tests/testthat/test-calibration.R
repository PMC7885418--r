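test_that("loss primitives match hand arithmetic", {
  Y <- rbind(c(1, 0), c(0, 1))
  expect_equal(inference_loss(Y, Y), 0)
  expect_equal(inference_loss(matrix(c(1, 0)), matrix(c(0, 0))), 1)
  # per-sample L1 errors (0.5 + 0.5) and (0 + 1), averaged
  expect_equal(inference_loss(rbind(c(0.5, 0), c(0.5, 1)),
                              matrix(0, 2, 2)), 1)
  expect_error(inference_loss(Y, matrix(0, 2, 3)), "shape")
  expect_equal(total_loss(1, 2, 0.01), 1.02)
  expect_equal(total_loss(5, 2, 0), 5)
  expect_equal(total_loss(0, 3, 0.25), 0.75)
})

test_that("contractive loss agrees with per-sample Jacobians and zero nets", {
  topo <- tiny_topology()
  expect_equal(contractive_loss(zero_params(topo), matrix(runif(9), 3, 3)), 0)
  p <- tiny_params(seed = 5)
  set.seed(20)
  E <- matrix(runif(3 * 4), 3, 4)
  # oracle: finite-difference Jacobians of the forward map, per sample
  fd_lc <- mean(sapply(1:4, function(t) {
    h <- 1e-4
    J <- sapply(1:3, function(i) {
      ep <- E[, t]; ep[i] <- ep[i] + h
      em <- E[, t]; em[i] <- em[i] - h
      (mrl_forward(p, ep)$output - mrl_forward(p, em)$output) / (2 * h)
    })
    sum(J^2) / (3 * 2)
  }))
  expect_equal(contractive_loss(p, E), fd_lc, tolerance = 1e-4)
})

test_that("corruption adds the configured Gaussian noise", {
  x <- matrix(runif(100), 10, 10)
  expect_identical(corrupt(x, 0), x)
  set.seed(21)
  big <- matrix(0, 1000, 1000)
  noise <- corrupt(big, 0.1) - big
  expect_equal(var(as.numeric(noise)), 0.1, tolerance = 0.01 * 0.1)
  set.seed(22); a <- corrupt(x, 0.05)
  set.seed(22); b <- corrupt(x, 0.05)
  expect_identical(a, b)
  expect_error(corrupt(x, -1), ">= 0")
})

test_that("validation splits are sized, disjoint and seed-deterministic", {
  set.seed(23)
  sp <- split_validation(1000, 0.10)
  expect_length(sp$validation, 100L)
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_setequal(c(sp$train, sp$validation), 1:1000)
  set.seed(24); s1 <- split_validation(50, 0.2)
  set.seed(24); s2 <- split_validation(50, 0.2)
  expect_identical(s1, s2)
  expect_error(split_validation(100, 0), "fraction")
  expect_error(split_validation(3, 0.01), "empty")
})

test_that("analytic gradients of the total loss match finite differences", {
  # double precision, small nets; relative tolerance 1e-3
  p <- tiny_params(seed = 9)
  set.seed(30)
  E <- matrix(runif(3 * 5), 3, 5)
  Y <- matrix(sample(c(-1, 0, 1), 10, replace = TRUE), 2, 5)
  loss_fn <- function(pp) myodecode:::mrl_engine(pp, E, Y, 0.01,
                                                 need_grad = FALSE,
                                                 need_tangent = TRUE)$L
  res <- myodecode:::mrl_engine(p, E, Y, 0.01, need_grad = TRUE,
                                need_tangent = TRUE)
  check <- function(getter, setter, g_analytic) {
    m <- getter(p)
    idx <- sample(length(m), min(5, length(m)))
    for (k in idx) {
      h <- 1e-5
      mp <- m; mp[k] <- mp[k] + h
      mm <- m; mm[k] <- mm[k] - h
      fd <- (loss_fn(setter(p, mp)) - loss_fn(setter(p, mm))) / (2 * h)
      denom <- max(abs(fd), abs(g_analytic[k]), 1e-6)
      expect_lt(abs(fd - g_analytic[k]) / denom, 1e-3)
    }
  }
  for (l in seq_along(p$encoder)) {
    check(function(q) q$encoder[[l]]$W,
          function(q, v) { q$encoder[[l]]$W <- v; q },
          res$grads$encoder[[l]]$W)
    check(function(q) q$encoder[[l]]$b,
          function(q, v) { q$encoder[[l]]$b <- v; q },
          res$grads$encoder[[l]]$b)
  }
  for (j in 1:2) for (part in c("hidden", "out")) {
    check(function(q) q$decoder[[j]][[part]]$W,
          function(q, v) { q$decoder[[j]][[part]]$W <- v; q },
          res$grads$decoder[[j]][[part]]$W)
  }
})

test_that("calibration descends, obeys the iteration cap and logs", {
  ses <- quick_session(seed = 31)
  pre <- preprocess_emg(ses$recording)
  topo <- mrl_topology(first_layer_log2 = 4, encoder_depth = 2,
                       decoder_hidden_log2 = 3)
  cfg <- mrl_config(batch_size = 128, max_iterations = 60, lookback = 50,
                    learning_rate = 3e-3, seed = 32)
  fit <- mrl_calibrate(pre$envelopes, ses$stimulus, topo, cfg)
  expect_s3_class(fit, "mrl_fit")
  expect_lte(nrow(fit$log), 60)
  expect_lt(mean(tail(fit$log$L_i, 10)), fit$log$L_i[1])
  expect_true(all(c("L", "L_i", "L_c", "L_v") %in% names(fit$log)))
  expect_true(fit$stop_reason %in% c("lookback", "max-iter"))
  expect_gte(fit$best_iteration, 1)
  expect_error(mrl_calibrate(pre$envelopes$values[, 1:10],
                             ses$stimulus$values[, 1:11], topo, cfg),
               "synchronous")
})

test_that("training configuration validates its fields", {
  expect_error(mrl_config(validation_fraction = 1.2))
  expect_error(mrl_config(contractive_weight = -1))
  expect_error(mrl_config(max_iterations = 0))
  cfg <- mrl_config()
  # reference defaults
  expect_equal(cfg$contractive_weight, 1e-2)
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$beta1, 0.9)
  expect_equal(cfg$beta2, 0.999)
  expect_equal(cfg$noise_variance, 0.1)
  expect_equal(cfg$weight_decay, 1e-6)
  expect_equal(cfg$batch_size, 4096)
  expect_equal(cfg$validation_fraction, 0.1)
  expect_equal(cfg$lookback, 300)
  expect_equal(cfg$max_iterations, 5000)
})
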