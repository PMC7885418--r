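test_that("subject profiles are deterministic, seed-sensitive and valid", {
  p1 <- make_subject_profile(seed = 1)
  p2 <- make_subject_profile(seed = 1)
  p3 <- make_subject_profile(seed = 2)
  expect_identical(p1, p2)
  expect_false(isTRUE(all.equal(p1$gains, p3$gains)))
  for (s in 1:10) {
    p <- make_subject_profile(seed = s)
    expect_true(all(p$gains >= 0))
    expect_true(all(apply(p$gains, 2, max) > 0))
    # antagonist directions are not collinear
    cosang <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    expect_lt(abs(cosang(p$gains[, 1], p$gains[, 2])), 0.999)
    expect_lt(abs(cosang(p$gains[, 3], p$gains[, 4])), 0.999)
  }
  expect_error(make_subject_profile(seed = 1, n_channels = 1), "invalid")
})

test_that("emg_sample respects the amplitude model and the ADC grid", {
  p <- make_subject_profile(seed = 3)
  expect_error(emg_sample(p, c(1.5, 0)), "intent")
  set.seed(42)
  # quantization: all samples on the 2^8-level grid inside the range
  x <- emg_sample(p, c(0.5, -0.5), n = 2000)
  delta <- 2 * p$v_range / 2^8
  expect_true(all(abs(x / delta - round(x / delta)) < 1e-9))
  expect_true(all(x >= -p$v_range & x < p$v_range))
  # rest: amplitude is baseline only
  set.seed(43)
  r <- emg_sample(p, c(0, 0), n = 20000)
  expect_true(all(abs(apply(r, 1, sd) - p$baseline_noise_sd) <
                    0.2 * p$baseline_noise_sd + delta))
  # Monte-Carlo monotonicity: doubling one intent component raises MAV on
  # gain > 0 channels (oracle: E|x| of the amplitude model grows with |intent|)
  set.seed(44)
  mav1 <- rowMeans(abs(emg_sample(p, c(0.25, 0), n = 10000)))
  mav2 <- rowMeans(abs(emg_sample(p, c(0.5, 0), n = 10000)))
  ch <- p$gains[, "wrist_extension"] > 0.05
  expect_true(all(mav2[ch] > mav1[ch]))
})

test_that("calibration sessions follow the protocol arithmetic and encodings", {
  p <- make_subject_profile(seed = 1)
  ses <- generate_calibration_session(p, acquisition_protocol(), seed = 9)
  # 8 movements x 3 reps x (5 s + 3 s) x 200 Hz
  expect_identical(ses$recording$n_samples, 8L * 3L * (5L + 3L) * 200L)
  expect_identical(dim(ses$stimulus$values), c(2L, 38400L))
  # leading rest occupies the first 3 s and is encoded [0, 0]
  expect_true(all(ses$stimulus$values[, 1:600] == 0))
  # stimulus uses exactly the ternary class encodings, block order m = 1..8
  cls <- encoding_to_class(ses$stimulus$values)
  expect_setequal(unique(cls), 0:8)
  block <- 3 * (3 + 5) * 200                      # one movement block
  m5 <- ses$stimulus$values[, (4 * block + 601):(4 * block + 700)]
  expect_true(all(m5[1, ] == -1 & m5[2, ] == -1)) # wrist + digit flexion
  # determinism
  ses2 <- generate_calibration_session(p, acquisition_protocol(), seed = 9)
  expect_identical(ses$recording$values, ses2$recording$values)
  # intent ramps are trapezoidal and capped at the contraction level
  expect_lte(max(abs(ses$intent)), 0.5)
})

test_that("MVC recordings are per-movement, 5 s, and stronger than 50% MVC", {
  p <- make_subject_profile(seed = 2)
  mvc <- generate_mvc_recordings(p, seed = 4)
  expect_length(mvc, 8L)
  expect_true(all(vapply(mvc, function(r) r$n_samples, integer(1)) == 1000L))
  set.seed(5)
  for (m in c(1, 4, 7)) {
    full <- rowMeans(abs(emg_sample(p, movement_encoding(m), n = 10000)))
    half <- rowMeans(abs(emg_sample(p, movement_encoding(m) * 0.5, n = 10000)))
    enc <- movement_encoding(m)
    act <- (p$gains %*% c(max(-enc[1], 0), max(enc[1], 0),
                          max(-enc[2], 0), max(enc[2], 0))) > 0.05
    expect_true(all(full[act] > half[act]))
  }
})

test_that("classes are linearly separable and envelopes track intent", {
  for (s in c(11, 12, 13)) {
    p <- make_subject_profile(seed = s)
    set.seed(s)
    feats <- NULL; labs <- NULL
    for (m in 0:8) {
      x <- emg_sample(p, movement_encoding(m) * 0.5, n = 100 * 32)
      mav <- sapply(seq_len(100), function(w)
        rowMeans(abs(x[, ((w - 1) * 32 + 1):(w * 32), drop = FALSE])))
      feats <- rbind(feats, t(mav))
      labs <- c(labs, rep(m, 100))
    }
    fit <- suppressWarnings(MASS::lda(feats, grouping = factor(labs)))
    pred <- predict(fit, feats)$class
    expect_gte(mean(pred == factor(labs)), 0.999)
  }
  # proportionality ground truth: envelope ~ |intent| on a slow ramp
  p <- make_subject_profile(seed = 11)
  set.seed(99)
  ramp <- seq(0, 1, length.out = 4000)
  x <- sapply(ramp, function(a) emg_sample(p, c(a, 0)))
  env <- extract_envelope(emg_recording(x, 200), 0.5)
  # channels whose gain clears the quantization floor
  ch <- p$gains[, "wrist_extension"] > 0.2
  for (i in which(ch)) {
    expect_gt(cor(env$values[i, 500:4000], ramp[500:4000]), 0.9)
  }
})
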