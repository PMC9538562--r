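test_that("valid proportion is 1 when every frame is valid", {
  coh <- stub_cohort(stub_trial(), stub_trial(repetition = 2))
  cur <- valid_proportion_curve(coh)
  expect_equal(cur$value, rep(1, 112))
  expect_equal(cur$denominator, rep(2, 112))
})

test_that("a single trial's curve equals its validity flags", {
  flags <- rep(c(TRUE, FALSE), 56)
  coh <- stub_cohort(stub_trial(valid = flags))
  cur <- valid_proportion_curve(coh)
  expect_equal(cur$value, as.numeric(flags))
  expect_equal(cur$denominator, rep(1, 112))
})

test_that("curve numerators conserve the cohort's valid-frame count", {
  coh <- generate_cohort(generator_params(n_subjects = 1), seed = 4)
  cur <- valid_proportion_curve(coh)
  expect_equal(sum(cur$numerator),
               sum(coh$valid[coh$source == "vision"]))
})

test_that("an empty cohort is rejected", {
  coh <- stub_cohort(stub_trial())
  expect_error(valid_proportion_curve(coh[0, ]), "empty cohort")
})

test_that("a strictly decreasing curve forces the minimum window", {
  cur <- stub_curve(seq(0.9, 0.2, length.out = 112))
  sp <- find_sweet_period(cur, min_window_frames = 5)
  expect_equal(c(sp$start, sp$end), c(0, 200))
  expect_equal(sp$frame_count, 5)
})

test_that("a constant curve picks the shortest admissible window", {
  cur <- stub_curve(rep(0.5, 112))
  sp <- find_sweet_period(cur, min_window_frames = 5)
  expect_equal(sp$end, 200)                       # tie broken toward short
  expect_equal(find_sweet_period(cur, 1)$end, 40)
})

test_that("the minimum-length rule can override a sharper short window", {
  # early plateau with a peak at frame 3 then a drop: unconstrained search
  # stops before the decline; the >=5-frame rule extends the window
  v <- c(0.50, 0.55, 0.60, 0.65, 0.50, 0.48, 0.46, 0.44,
         rep(0.1, 104))
  cur <- stub_curve(v)
  free <- find_sweet_period(cur, min_window_frames = 1)
  constrained <- find_sweet_period(cur, min_window_frames = 5)
  o1 <- oracle_sweet_period(v, 1)
  o5 <- oracle_sweet_period(v, 5)
  expect_equal(free$end, o1$end)
  expect_equal(constrained$end, o5$end)
  expect_lt(free$end, constrained$end)
  expect_equal(free$end, 160)                     # ends before the decline
})

test_that("window search agrees with brute force on random curves", {
  set.seed(99)
  for (i in 1:1000) {
    len <- sample(6:40, 1)
    v <- runif(len)
    mf <- sample(1:5, 1)
    sp <- find_sweet_period(stub_curve(v), min_window_frames = mf)
    o <- oracle_sweet_period(v, mf)
    expect_equal(sp$end, o$end)
    expect_equal(sp$score, o$score)
    expect_equal(sp$frame_count, o$frames)
  }
})

test_that("relaxing the length constraint never lowers the best score", {
  set.seed(7)
  for (i in 1:200) {
    v <- runif(sample(6:30, 1))
    cur <- stub_curve(v)
    expect_gte(find_sweet_period(cur, 1)$score,
               find_sweet_period(cur, 5)$score)
  }
})

test_that("window search rejects impossible minimum lengths", {
  cur <- stub_curve(runif(10))
  expect_error(find_sweet_period(cur, 11), "exceeds the trial length")
  expect_error(find_sweet_period(cur, 0), ">= 1")
})

test_that("candidate scores are reported for every anchored window", {
  v <- runif(20)
  sp <- find_sweet_period(stub_curve(v), 5)
  expect_equal(nrow(sp$candidates), 20)
  expect_equal(sp$candidates$score, cumsum(v) / seq_along(v))
  expect_equal(sum(sp$candidates$admissible), 16)
})

test_that("accuracy curves are exact on hand-built streams", {
  # trial 1: valid frames 0..3 with one gesture error at frame 1
  pg <- rep(2L, 112); pg[2] <- 9L
  t1 <- stub_trial(gesture = 2, object = "Key",
                   valid = c(rep(TRUE, 4), rep(FALSE, 108)),
                   pred_gesture = pg)
  # trial 2: all frames invalid
  t2 <- stub_trial(gesture = 2, object = "Plate", repetition = 1,
                   subject = 2, valid = rep(FALSE, 112))
  coh <- stub_cohort(t1, t2)
  cur <- accuracy_curve(coh, "gesture_vision")
  expect_equal(cur$value[1:4], c(1, 0, 1, 1))
  expect_true(all(is.na(cur$value[5:112])))       # undefined, not zero
  expect_equal(cur$denominator[1:5], c(1, 1, 1, 1, 0))
})

test_that("the sEMG accuracy curve uses all trials as denominator", {
  e1 <- rep(4L, 112); e1[1] <- 8L
  t1 <- stub_trial(gesture = 4, object = "Mug", emg_pred = e1)
  t2 <- stub_trial(gesture = 4, object = "Drawer", emg_pred = rep(5L, 112))
  cur <- accuracy_curve(stub_cohort(t1, t2), "emg")
  expect_equal(cur$denominator, rep(2, 112))
  expect_equal(cur$value[1], 0)                    # 8 and 5: both wrong
  expect_equal(cur$value[2], 0.5)
})

test_that("noiseless cohorts give unit accuracy wherever defined", {
  coh <- stub_cohort(stub_trial(), stub_trial(repetition = 2))
  for (src in c("gesture_vision", "object_vision", "emg")) {
    cur <- accuracy_curve(coh, src)
    expect_true(all(cur$value[cur$denominator > 0] == 1))
  }
})

test_that("window accuracy pools counts over valid frames", {
  pg <- rep(6L, 112); pg[2] <- 1L                  # 1 error in 4 valid frames
  t1 <- stub_trial(gesture = 6, object = "Bulb",
                   valid = c(rep(TRUE, 4), rep(FALSE, 108)),
                   pred_gesture = pg)
  coh <- stub_cohort(t1)
  res <- window_mean_accuracy(coh, "gesture_vision", c(0, 320))
  expect_equal(res$accuracy, 0.75)
  expect_equal(res$total, 4)
  none <- window_mean_accuracy(coh, "gesture_vision", c(1600, 1920))
  expect_true(is.na(none$accuracy))
  expect_equal(none$total, 0)
  full <- window_mean_accuracy(coh, "emg", c(1100, 1400))
  expect_equal(full$accuracy, 1)
  expect_equal(full$total, 7)                      # 40 ms points in [1100,1400)
})

test_that("window accuracy validates the window", {
  coh <- stub_cohort(stub_trial())
  expect_error(window_mean_accuracy(coh, "emg", c(-40, 320)), "within")
  expect_error(window_mean_accuracy(coh, "emg", c(320, 320)), "start < end")
})
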