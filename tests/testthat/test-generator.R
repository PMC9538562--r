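test_that("the validity curve is the documented piecewise-linear shape", {
  p <- generator_params()
  expect_equal(validity_probability(p, 0), p$baseline)
  expect_equal(validity_probability(p, p$peak_time), p$peak)
  expect_equal(validity_probability(p, p$decline_end), p$floor)
  expect_equal(validity_probability(p, 4479), p$floor)   # firm-grasp plateau
  expect_equal(validity_probability(p, 4480), p$floor)
  # continuity across the kinks
  eps <- 1e-6
  for (t0 in c(p$peak_time, p$decline_end))
    expect_equal(validity_probability(p, t0 - eps),
                 validity_probability(p, t0 + eps), tolerance = 1e-4)
  # monotone rise then monotone decline
  tt <- seq(0, p$peak_time, by = 10)
  expect_true(all(diff(validity_probability(p, tt)) >= 0))
  tt <- seq(p$peak_time, p$decline_end, by = 10)
  expect_true(all(diff(validity_probability(p, tt)) <= 0))
})

test_that("expected_validity_curve reduces to the raw curve without jitter", {
  p0 <- generator_params(jitter = 0)
  expect_equal(expected_validity_curve(p0),
               validity_probability(p0, frame_times(p0$timeline)))
})

test_that("a noiseless generator yields perfect, fully valid streams", {
  p <- generator_params(baseline = 1, peak = 1, floor = 1, jitter = 0,
                        acc_gesture = 1, acc_object = 1,
                        emg_accuracy = 1, emg_consistency = 1)
  tr <- generate_trial(p, subject = 1, gesture = 3, object = "Book",
                       repetition = 2, seed = 9)
  vis <- tr[tr$source == "vision", ]
  emg <- tr[tr$source == "emg", ]
  expect_equal(nrow(vis), 112)
  expect_true(all(vis$valid))
  expect_true(all(vis$pred_gesture == 3))
  expect_true(all(vis$pred_object == "Book"))
  expect_true(all(emg$pred_gesture == 3))
})

test_that("a zero validity curve gives no valid frames and absent vision", {
  p <- generator_params(baseline = 0, peak = 0, floor = 0, jitter = 0)
  tr <- generate_trial(p, 1, 1, "Bottle", 1, seed = 2)
  vis <- tr[tr$source == "vision", ]
  expect_false(any(vis$valid))
  expect_true(all(is.na(vis$pred_gesture)))
  d <- vision_decision(tr, c(0, 320))
  expect_false(d$present)
  expect_equal(d$confidence, 0)
})

test_that("trials are reproducible and independent of generation order", {
  p <- generator_params(n_subjects = 2)
  expect_identical(generate_trial(p, 2, 5, "Jar", 3, seed = 11),
                   generate_trial(p, 2, 5, "Jar", 3, seed = 11))
  coh <- generate_cohort(p, seed = 11)
  sel <- coh$subject == 2 & coh$gesture == 5 & coh$object == "Jar" &
    coh$repetition == 3
  sub <- as.data.frame(coh[sel, ])
  rownames(sub) <- NULL
  one <- generate_trial(p, 2, 5, "Jar", 3, seed = 11)
  attr(one, "timeline") <- NULL
  attr(sub, "timeline") <- NULL
  expect_equal(sub, one)
})

test_that("same seed reproduces a cohort, different seeds differ", {
  p <- generator_params(n_subjects = 1)
  a <- generate_cohort(p, seed = 5)
  b <- generate_cohort(p, seed = 5)
  c <- generate_cohort(p, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$valid, c$valid))
})

test_that("cohort dimensions follow the crossed design", {
  p <- generator_params(n_subjects = 1)
  coh <- generate_cohort(p, seed = 1)
  trials <- unique(coh[coh$source == "vision",
                       c("subject", "gesture", "object", "repetition")])
  expect_equal(nrow(trials), 120)          # 30 pairs x 4 repetitions
  expect_equal(sum(coh$source == "vision"), 120 * 112)
  expect_equal(sum(coh$source == "emg"), 120 * 112)
  expect_true(all(table(coh$gesture[coh$source == "vision"],
                        coh$repetition[coh$source == "vision"]) > 0))
})

test_that("generate_trial rejects a gesture-object pair not in the taxonomy", {
  p <- generator_params()
  expect_error(generate_trial(p, 1, 1, "Book", 1), "not a taxonomy pair")
})

test_that("per-frame validity tracks the jitter-averaged marginal", {
  p <- generator_params(n_subjects = 5)          # 600 trials
  coh <- generate_cohort(p, seed = 21)
  cur <- valid_proportion_curve(coh)
  expected <- expected_validity_curve(p)
  n <- cur$denominator[1]
  se <- sqrt(pmax(expected * (1 - expected), 1e-12) / n)
  expect_true(all(abs(cur$value - expected) <= 3 * se + 1e-9))
})

test_that("vision accuracies among valid frames recover the parameters", {
  p <- generator_params(n_subjects = 5, acc_gesture = 0.8, acc_object = 0.9)
  coh <- generate_cohort(p, seed = 22)
  vis <- coh[coh$source == "vision" & coh$valid %in% TRUE, ]
  n <- nrow(vis)
  expect_gt(n, 5000)
  for (chk in list(list(mean(vis$pred_gesture == vis$true_gesture), 0.8),
                   list(mean(vis$pred_object == vis$object), 0.9))) {
    se <- sqrt(chk[[2]] * (1 - chk[[2]]) / n)
    expect_lt(abs(chk[[1]] - chk[[2]]), 4 * se)
  }
})

test_that("vision gesture errors are uniform over the nine other labels", {
  p <- generator_params(n_subjects = 4, acc_gesture = 0.5, jitter = 0,
                        baseline = 0.9, peak = 0.9, floor = 0.9)
  coh <- generate_cohort(p, seed = 23)
  vis <- coh[coh$source == "vision" & coh$valid %in% TRUE, ]
  errs <- vis[vis$pred_gesture != vis$true_gesture & vis$true_gesture == 1, ]
  expect_gt(nrow(errs), 500)
  tab <- table(factor(errs$pred_gesture, levels = 2:10))
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
})

test_that("a gesture confusion table steers the error labels", {
  conf <- matrix(0, 10, 10)
  conf[1, 7] <- 1                                # gesture 1 errs only to 7
  p <- generator_params(n_subjects = 1, acc_gesture = 0.5,
                        gesture_confusion = conf, jitter = 0,
                        baseline = 1, peak = 1, floor = 1)
  coh <- generate_cohort(p, seed = 8)
  vis <- coh[coh$source == "vision" & coh$valid %in% TRUE &
               coh$true_gesture == 1, ]
  wrong <- vis$pred_gesture[vis$pred_gesture != 1]
  expect_gt(length(wrong), 50)
  expect_true(all(wrong == 7))
})

test_that("sEMG streams have a dominant per-trial label", {
  p <- generator_params(n_subjects = 2)
  coh <- generate_cohort(p, seed = 31)
  emg <- coh[coh$source == "emg", ]
  id <- paste(emg$subject, emg$gesture, emg$object, emg$repetition)
  top_share <- vapply(split(emg$pred_gesture, id), function(v)
    max(table(v)) / length(v), numeric(1))
  # consistency 0.93 over 112 points: the dominant label towers over noise
  expect_gt(mean(top_share > 0.85), 0.9)
  dom_correct <- vapply(split(emg[c("pred_gesture", "true_gesture")], id),
                        function(d) {
                          tb <- table(d$pred_gesture)
                          as.integer(names(tb)[which.max(tb)]) ==
                            d$true_gesture[1]
                        }, logical(1))
  se <- sqrt(0.855 * 0.145 / length(dom_correct))
  expect_lt(abs(mean(dom_correct) - 0.855), 4 * se)
})
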