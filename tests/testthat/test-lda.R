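test_that("time-domain features match hand enumeration", {
  f <- td_features(c(1, -1, 1, -1))
  expect_equal(unname(f), c(1, 3, 2, 6))  # mav, zc, ssc, wl
  expect_equal(unname(td_features(c(0, 1, 0, 1))[["ssc"]]), 2)
  cst <- td_features(rep(2, 10))
  expect_equal(unname(cst), c(2, 0, 0, 0))
  expect_error(td_features(1), "too short")
  # thresholds suppress small crossings
  expect_equal(unname(td_features(c(0.1, -0.1, 0.1), zc_threshold = 1)[["zc"]]), 0)
  # the compiled all-channel kernel agrees with the scalar reference
  set.seed(40)
  X <- matrix(rnorm(4 * 32), 4, 32)
  expect_equal(as.numeric(apply(X, 1, td_features)),
               as.numeric(myodecode:::.td_features_all_cpp(X, 0, 0)))
})

test_that("window streaming obeys the count formula and majority voting", {
  # count formula vs brute force for assorted lengths
  for (Tn in c(32, 33, 35, 100, 1000)) {
    rec <- emg_recording(matrix(rnorm(Tn), 1, Tn), 200)
    ws <- window_stream(rec, window = 32L, increment = 3L)
    brute <- length(seq(1, Tn - 32 + 1, by = 3))
    expect_identical(nrow(ws$features), brute)
    expect_identical(nrow(ws$features), as.integer(floor((Tn - 32) / 3) + 1))
  }
  expect_error(window_stream(emg_recording(matrix(0, 1, 10), 200)), "shorter")
  # labels: fully inside a wrist-flexion segment -> class 1;
  # 17 rest + 15 movement samples -> rest by majority
  stim <- matrix(0, 2, 64)
  stim[1, 18:64] <- -1                      # flexion from sample 18 on
  rec <- emg_recording(matrix(rnorm(2 * 64), 2, 64), 200)
  ws <- window_stream(rec, stimulus_encoding(stim))
  expect_identical(ws$labels[1], 0L)        # window 1..32: 17 rest, 15 move
  expect_identical(ws$labels[11], 1L)       # window 31..62: fully flexion
})

test_that("fitting produces exact proportionality tables and catches gaps", {
  ses <- quick_session(seed = 41)
  ws <- window_stream(ses$recording, ses$stimulus)
  model <- lda_fit(ws$features, ws$labels, n_channels = 8)
  # Eq. identity: C is the channel sum of S
  expect_equal(model$tables$C, colSums(model$tables$S))
  expect_true(all(model$tables$S >= 0))
  # S entries are plain class means of raw MAVs
  mav_cols <- seq(1, by = 4, length.out = 8)
  for (m in c(0, 3, 8)) {
    expect_equal(model$tables$S[, m + 1],
                 colMeans(ws$features[ws$labels == m, mav_cols]))
  }
  # missing class is refused by name
  drop <- ws$labels != 4
  expect_error(lda_fit(ws$features[drop, ], ws$labels[drop]), "class\\(es\\) 4")
})

test_that("classification is deterministic, invariant to feature shifts", {
  ses <- quick_session(seed = 42)
  ws <- window_stream(ses$recording, ses$stimulus)
  model <- lda_fit(ws$features, ws$labels)
  pred <- lda_classify(model, ws$features)
  # a class-mean feature vector classifies to its own class
  for (m in 0:8) {
    mu <- colMeans(ws$features[ws$labels == m, , drop = FALSE])
    expect_identical(lda_classify(model, mu), m)
  }
  # adding a constant to a single feature everywhere is absorbed by the scaler
  shifted <- ws$features
  shifted[, 7] <- shifted[, 7] + 100
  model2 <- lda_fit(shifted, ws$labels)
  expect_identical(lda_classify(model2, shifted), pred)
  # tie-break: identical discriminants resolve to the lowest class id
  tie <- model
  tie$discriminant$A[, 2] <- tie$discriminant$A[, 5]
  tie$discriminant$c0[2] <- tie$discriminant$c0[5]
  mu4 <- colMeans(ws$features[ws$labels == 4, , drop = FALSE])
  expect_identical(lda_classify(tie, mu4), 1L)
  expect_error(lda_classify(list(), ws$features[1, ]), "fitted")
})

test_that("the proportionality scalar implements its defining algebra", {
  tables <- list(S = matrix(c(0, 2, 0, 3), 1, 4), C = c(0, 2, 0, 3),
                 classes = 0:3)
  # single channel: PC reduces to the squared MAV
  expect_equal(lda_proportionality(5, 1, tables), 25)
  expect_equal(lda_proportionality(0, 1, tables), 0)
  expect_error(lda_proportionality(5, 0, tables), "non-rest")
  expect_error(lda_proportionality(5, 2, tables), "degenerate")
  # uniform S row: PC is the squared mean MAV; scale law PC(k v) = k^2 PC(v)
  tab2 <- list(S = matrix(1, 8, 2), C = c(8, 8), classes = 0:1)
  v <- runif(8)
  expect_equal(lda_proportionality(rep(0.3, 8), 1, tab2), 0.09)
  expect_equal(lda_proportionality(3 * v, 1, tab2),
               9 * lda_proportionality(v, 1, tab2))
})

test_that("MVC magnitude is the max sliding channel-summed MAV", {
  cst <- emg_recording(matrix(0.5, 8, 400), 200)
  expect_equal(mvc_magnitude(cst), 8 * 0.5)
  set.seed(43)
  x <- matrix(rnorm(2 * 500), 2, 500)
  expect_equal(mvc_magnitude(emg_recording(3 * x, 200)),
               3 * mvc_magnitude(emg_recording(x, 200)))
  # brute-force oracle on a ramp: the last window wins
  ramp <- matrix(seq(0, 1, length.out = 300), 1, 300)
  rec <- emg_recording(ramp, 200)
  W <- 100
  brute <- max(sapply(1:(300 - W + 1), function(s) mean(ramp[s:(s + W - 1)])))
  expect_equal(mvc_magnitude(rec), brute)
  expect_error(mvc_magnitude(emg_recording(matrix(1, 1, 50), 200)), "short")
})

test_that("held-out window accuracy is high on a separable synthetic session", {
  prof <- make_subject_profile(seed = 44)
  ses <- generate_calibration_session(prof, acquisition_protocol(), seed = 45)
  ws <- window_stream(ses$recording, ses$stimulus)
  set.seed(46)
  hold <- sample(nrow(ws$features), round(0.1 * nrow(ws$features)))
  model <- lda_fit(ws$features[-hold, ], ws$labels[-hold])
  acc <- mean(lda_classify(model, ws$features[hold, ]) == ws$labels[hold])
  expect_gte(acc, 0.9)
})
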