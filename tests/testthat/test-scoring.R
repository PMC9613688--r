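test_that("latency is measured from the response-frame onset", {
  sch <- build_schedule("2D-P", seed = 1)
  sim <- simulate_gaze(sch, quiet_subject(latency_mean = 0.18), 120, seed = 1)
  sc <- score_trials(sim$trace, sch)
  expect_true(all(sc$valid))
  expect_true(all(sc$reason == "ok"))
  # detection may lead the true onset by up to about one sample period
  expect_lt(abs(mean(sc$latency) - 0.18), 1 / 120 + 0.003)
  expect_true(all(sc$correct))
})

test_that("anti-saccade trials toward the stimulus are scored as errors", {
  sch <- build_schedule("2D-A", seed = 2)
  sim <- simulate_gaze(sch, quiet_subject(error_prob = 1), 120, seed = 2)
  sc <- score_trials(sim$trace, sch)
  expect_true(all(!sc$correct[sc$valid]))
  expect_equal(aggregate_condition(sc)$error_rate, 1)
})

test_that("anticipatory saccades invalidate the trial", {
  sch <- build_schedule("2D-P", seed = 3)
  s <- quiet_subject(latency_mean = 0.03, latency_floor = 0.02)
  sim <- simulate_gaze(sch, s, 120, seed = 3)
  sc <- score_trials(sim$trace, sch, anticipation_floor = 0.08)
  expect_true(all(!sc$valid))
  expect_true(all(sc$reason == "anticipatory"))
})

test_that("windows without saccades and long gaps get reason codes", {
  sch <- build_schedule("2D-P", seed = 4)
  n <- 80 * 120
  flat <- tibble::new_tibble(
    list(t = (0:(n - 1)) / 120, gaze_h = rep(0, n), gaze_v = rep(0, n),
         pupil = rep(3.5, n), valid = rep(TRUE, n)),
    nrow = n, class = "gaze_trace", sample_rate = 120
  )
  sc <- score_trials(flat, sch)
  expect_true(all(!sc$valid))
  expect_true(all(sc$reason == "no_saccade"))
  expect_true(all(is.na(sc$latency)))

  sim <- simulate_gaze(sch, quiet_subject(), 120, seed = 4)
  tr <- sim$trace
  w1 <- response_events(sch)$t_onset[1]
  tr$valid[tr$t >= w1 + 0.3 & tr$t <= w1 + 0.55] <- FALSE
  sc2 <- score_trials(tr, sch)
  expect_equal(sc2$reason[1], "data_gap")
  expect_true(all(sc2$reason[-1] == "ok"))
})

test_that("gaze-duration rule picks the longest-dwelled target", {
  mk <- function(gh) {
    n <- length(gh)
    tibble::new_tibble(
      list(t = (0:(n - 1)) / 100, gaze_h = gh, gaze_v = rep(0, n),
           pupil = rep(3.5, n), valid = rep(TRUE, n)),
      nrow = n, class = "gaze_trace", sample_rate = 100
    )
  }
  # 1.2 s right, 0.4 s left, rest centre
  gh <- c(rep(8, 120), rep(-8, 40), rep(0, 90))
  out <- gaze_duration_target(mk(gh), c(0, 2.5))
  expect_equal(out$side, "right")
  expect_equal(out$dwell_right, 1.2)
  expect_equal(out$dwell_left, 0.4)
  expect_false(out$tie)

  centre <- gaze_duration_target(mk(rep(0, 250)), c(0, 2.5))
  expect_equal(centre$side, "none")
  expect_equal(centre$dwell_left + centre$dwell_right, 0)

  tie <- gaze_duration_target(mk(c(rep(8, 50), rep(-8, 50), rep(0, 150))),
                              c(0, 2.5))
  expect_equal(tie$side, "none")
  expect_true(tie$tie)

  expect_error(gaze_duration_target(mk(rep(0, 250)), c(0, 2.5),
                                    left_roi = c(-4, 1), right_roi = c(0, 4)),
               "overlap")
})

test_that("VM/SO trials use the dwell rule for correctness", {
  sch <- build_schedule("VM-P", seed = 5)
  sim <- simulate_gaze(sch, quiet_subject(), 120, seed = 5)
  sc <- score_trials(sim$trace, sch)
  expect_true(all(sc$valid))
  expect_true(all(sc$correct))
  expect_true(all(sc$dwell_side == sc$expected))

  # all-error subject: dwell lands on the wrong side
  sim_err <- simulate_gaze(sch, quiet_subject(error_prob = 1), 120, seed = 5)
  sc_err <- score_trials(sim_err$trace, sch)
  expect_true(all(!sc_err$correct))
})

test_that("aggregation computes the documented summary statistics", {
  scores <- tibble::tibble(
    trial = 1:30, t_response = 0, expected = "left",
    latency = rep(0.2, 30), peak_speed = rep(300, 30),
    amplitude = 8, direction = "left", dwell_side = NA, dwell_tie = NA,
    correct = c(rep(FALSE, 3), rep(TRUE, 27)),
    valid = TRUE, reason = "ok"
  )
  agg <- aggregate_condition(scores)
  expect_equal(agg$error_rate, 0.1)
  expect_equal(agg$latency_mean, 0.2)
  expect_equal(agg$latency_sd, 0)
  expect_equal(agg$n_valid, 30L)

  # alternative denominator counts invalid trials too
  scores$valid[1:10] <- FALSE
  expect_equal(aggregate_condition(scores, "all")$error_rate,
               sum(!scores$correct[scores$valid]) / 30)

  none <- scores[0, ]
  empty <- aggregate_condition(none)
  expect_true(empty$degenerate)
  expect_true(is.na(empty$latency_mean))
})

test_that("oculometrics recover the generating latency within 2 SE", {
  sch <- build_schedule("2D-P", seed = 6)
  s <- subject_model(latency_mean = 0.25, latency_sd = 0.05,
                     error_prob = 0.1, gaze_noise_sd = 0.1)
  sim <- simulate_gaze(sch, s, 120, seed = 6)
  agg <- aggregate_condition(score_trials(sim$trace, sch))
  se <- 0.05 / sqrt(agg$n_valid)
  expect_lt(abs(agg$latency_mean - 0.25), 2 * se + 1 / 120)
})
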