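test_that("the target layout matches the published geometry", {
  tg <- make_target_set()
  expect_identical(nrow(tg), 40L)
  expect_setequal(unique(tg$radius), c(60, 85))
  expect_equal(ceiling(sqrt(2) * 60), 85)  # large radius definition
  # 6 distinct difficulty values spanning 1.17 - 2.38 bits
  ids <- sort(unique(round(tg$id_bits, 2)))
  expect_length(ids, 6L)
  expect_equal(min(ids), 1.17, tolerance = 0.005)
  expect_equal(max(ids), 2.38, tolerance = 0.005)
  # no target on a coordinate axis
  expect_true(all(abs(tg$x) > 1 & abs(tg$y) > 1))
  # 5 centers per quadrant
  quad <- table(sign(tg$x), sign(tg$y))
  expect_true(all(quad == 10))
  expect_error(make_target_set(angles_deg = c(0, 30, 45, 60, 75)), "axis")
  expect_error(make_target_set(angles_deg = c(30, 45)), "5 angles")
})

test_that("velocity mappings scale to 540 px/s at unit command", {
  expect_equal(mrl_velocity(c(0, 0)), c(0, 0))
  expect_equal(mrl_velocity(c(0.5, 0)), c(270, 0))
  v <- mrl_velocity(c(1 / sqrt(2), -1 / sqrt(2)))
  expect_equal(sqrt(sum(v^2)), 540)
  expect_equal(lda_velocity(0, 5), c(0, 0))
  expect_equal(lda_velocity(2, 1), c(540, 0))       # wrist extension -> right
  expect_equal(lda_velocity(1, 1), c(-540, 0))      # wrist flexion -> left
  expect_equal(lda_velocity(8, 1), 540 * c(1, 1) / sqrt(2))  # diagonal
  expect_equal(lda_velocity(8, 0.5), 270 * c(1, 1) / sqrt(2))  # linear in PC
})

test_that("the trial state machine computes dwell, clock and overshoot exactly", {
  prof <- make_subject_profile(seed = 50)
  user <- simulated_user()
  target <- data.frame(x = 270, y = 0, radius = 60, distance = 270,
                       diameter = 120,
                       id_bits = index_of_difficulty(270, 120))
  # straight scripted run at 540 px/s: position 2.7 k px after k steps;
  # strictly inside after 2.7 k > 210 (k = 78), dwell 60 samples -> k = 137
  ctrl <- scripted_controller(function(t, cursor) {
    if (cursor[1] < 270) c(540, 0) else c(0, 0)  # stop on arrival
  })
  set.seed(51)
  log <- run_trial(ctrl, target, user, prof)
  expect_identical(log$outcome, "success")
  expect_equal(log$completion_time, 137 / 200)
  expect_equal(log$overshoots, 0L)
  expect_equal(log$trajectory[1, ], c(0, 0))
  # zero controller times out as a failure at 20 s
  set.seed(52)
  log0 <- run_trial(scripted_controller(function(t, cursor) c(0, 0)),
                    target, user, prof)
  expect_identical(log0$outcome, "failure")
  expect_true(is.na(log0$completion_time))
  expect_identical(nrow(log0$trajectory), 4001L)
  # enter, exit once, re-enter and dwell -> exactly one overshoot
  vfn <- function(t, cursor) {
    if (t <= 0.5) c(540, 0)          # fly to the center
    else if (t <= 0.7) c(540, 0)     # keep going, exits at ~0.61 s
    else if (t <= 1.0) c(-540, 0)    # come back
    else c(0, 0)                     # park inside
  }
  set.seed(53)
  log1 <- run_trial(scripted_controller(vfn), target, user, prof)
  expect_identical(log1$outcome, "success")
  expect_identical(log1$overshoots, 1L)
})

test_that("dwell and clock invariants hold for adversarial scripted paths", {
  prof <- make_subject_profile(seed = 54)
  user <- simulated_user()
  target <- data.frame(x = 120, y = 0, radius = 50, distance = 120,
                       diameter = 100, id_bits = index_of_difficulty(120, 100))
  # oscillator that never stays inside 0.3 s: must fail with many overshoots
  # hovers around x = 168, straddling the x = 170 boundary
  osc <- scripted_controller(function(t, cursor) {
    if (cursor[1] < 168) c(900, 0) else c(-900, 0)
  })
  set.seed(55)
  log <- run_trial(osc, target, user, prof, timeout = 5)
  expect_identical(log$outcome, "failure")
  expect_gt(log$overshoots, 5)
  # success requires 60 consecutive in-target samples (checked on the log)
  inside <- sqrt((log$trajectory[, 1] - 120)^2 + log$trajectory[, 2]^2) < 50
  runs <- rle(inside)
  expect_lt(max(runs$lengths[runs$values]), 60)
})

test_that("the simulated user stops at the center and is reproducible", {
  u <- simulated_user()
  set.seed(56)
  expect_equal(myodecode:::user_intent_raw(u, c(100, 50), c(100, 50)), c(0, 0))
  i1 <- myodecode:::user_intent_raw(u, c(0, 0), c(200, 0))
  expect_lte(sqrt(sum(i1^2)), u$max_intent + 1e-12)
  prof <- make_subject_profile(seed = 57)
  target <- make_target_set()[3, , drop = FALSE]
  ctrl <- scripted_controller(function(t, cursor) c(300, 100))
  set.seed(58); a <- run_trial(ctrl, target, u, prof)
  set.seed(58); b <- run_trial(ctrl, target, u, prof)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$outcome, b$outcome)
})

test_that("sessions visit all 40 targets once in a seed-dependent order", {
  prof <- make_subject_profile(seed = 59)
  tg <- make_target_set()
  user <- simulated_user()
  fast <- function(t, cursor) c(0, 0)  # all-fail controller, cheap trials
  ctrl <- scripted_controller(fast)
  logs <- run_session(ctrl, tg, user, prof, seed = 60, timeout = 0.1,
                      hold_seconds = 0.1, rest_seconds = 0.1)
  expect_length(logs, 40L)
  seen <- t(vapply(logs, function(l) c(l$target$x, l$target$y, l$target$radius),
                   numeric(3)))
  expect_identical(nrow(unique(seen)), 40L)
  expect_true(all(vapply(logs, function(l) all(l$trajectory[1, ] == c(0, 0)),
                         logical(1))))
  logs2 <- run_session(ctrl, tg, user, prof, seed = 61, timeout = 0.1,
                       hold_seconds = 0.1, rest_seconds = 0.1)
  seen2 <- t(vapply(logs2, function(l) c(l$target$x, l$target$y, l$target$radius),
                    numeric(3)))
  expect_false(identical(seen, seen2))
})
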