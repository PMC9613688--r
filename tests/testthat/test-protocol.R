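test_that("condition table encodes the 11-condition dual-task design", {
  tab <- condition_table()
  expect_equal(nrow(tab), 11)
  expect_equal(anyDuplicated(tab$name), 0)

  c4 <- tab[tab$index == 4, ]
  expect_equal(c4$name, "2D-P")
  expect_equal(c4$oculomotor_task, "pro")
  expect_true(c4$flag_posture && c4$flag_saccade)
  expect_false(c4$flag_vm || c4$flag_so || c4$flag_vc)

  c2 <- tab[tab$index == 2, ]
  expect_equal(c2$name, "EC")
  expect_equal(c2$oculomotor_task, "none")
  expect_true(c2$flag_posture)
  expect_false(c2$flag_saccade)

  c8 <- tab[tab$index == 8, ]
  expect_true(c8$flag_posture && c8$flag_saccade && c8$flag_vm)
  expect_false(c8$flag_so || c8$flag_vc)

  c11 <- tab[tab$index == 11, ]
  expect_equal(c11$name, "SO-A")
  expect_true(c11$flag_posture && c11$flag_saccade && c11$flag_so)

  # eyes-open/closed baselines: gaze or nothing, never a saccade task
  eoec <- tab[tab$environment %in% c("EO", "EC"), ]
  expect_true(all(eoec$oculomotor_task %in% c("gaze", "none")))
  expect_false(any(eoec$flag_saccade))
})

test_that("schedules realize the per-environment cycle structure", {
  cases <- list(
    list(cond = "2D-P", cycle = 2.0, np = 10, nr = 30),
    list(cond = "3D-A", cycle = 2.0, np = 10, nr = 30),
    list(cond = "VM-A", cycle = 10.0, np = 5, nr = 15),
    list(cond = "SO-P", cycle = 7.5, np = 5, nr = 15)
  )
  for (cs in cases) {
    sch <- build_schedule(cs$cond, seed = 7)
    expect_equal(sch$cycle_duration, cs$cycle)
    expect_equal(sch$n_practice, cs$np)
    expect_equal(sch$n_recorded, cs$nr)
    expect_equal(sch$duration, (cs$np + cs$nr) * cs$cycle)
    expect_equal(sch$posture_recording_start, cs$np * cs$cycle)
    ev <- sch$events
    expect_true(all(diff(ev$t_onset) > 0))
    expect_equal(sum(ev$duration), sch$duration)
    expect_equal(sum(ev$is_practice[ev$frame_kind %in%
                                      c("target", "response")]), cs$np)
    resp <- response_events(sch)
    expect_equal(nrow(resp), cs$nr)
    expect_true(all(resp$side %in% c("left", "right")))
    expect_true(all(resp$eccentricity == 8))
    expect_true(all(!is.na(resp$expected)))
  }

  # 2D-P example: 40 cycles, 80 s
  sch <- build_schedule("2D-P", seed = 1)
  expect_equal(max(sch$events$trial), 40)
  expect_equal(sch$duration, 80)

  # VM memorise frames hold two distinct symbols at +/-2 degrees
  vm <- build_schedule("VM-A", seed = 7)
  mem <- vm$events[vm$events$frame_kind == "memorise" & !vm$events$is_practice, ]
  expect_equal(nrow(mem), 15)
  expect_true(all(mem$duration == 2.5))
  expect_true(all(mem$eccentricity == 2))
  expect_true(all(mem$symbol != mem$symbol_other))

  # SO cycles: fixation, combined-view, response frames of 2.5 s each
  so <- build_schedule("SO-P", seed = 3)
  kinds <- so$events$frame_kind[so$events$trial == 6]
  expect_equal(kinds, c("central_fixation", "allocentric_view", "response"))
  expect_true(all(so$events$duration == 2.5))
})

test_that("recorded sides are balanced and runs are capped for many seeds", {
  for (seed in 1:40) {
    for (cond in c("2D-P", "VM-A", "SO-P")) {
      sch <- build_schedule(cond, seed = seed)
      resp <- response_events(sch)
      all_resp <- response_events(sch, recorded_only = FALSE)
      nl <- sum(resp$side == "left"); nr <- sum(resp$side == "right")
      if (sch$n_recorded %% 2 == 0) {
        expect_equal(nl, nr)
      } else {
        expect_lte(abs(nl - nr), 1)
      }
      # whole schedule always exactly balanced
      expect_equal(sum(all_resp$side == "left"),
                   sum(all_resp$side == "right"))
      expect_lte(max(rle(all_resp$side)$lengths), 3)
    }
  }
})

test_that("schedules are reproducible under a fixed seed", {
  a <- build_schedule("2D-P", seed = 1)
  b <- build_schedule("2D-P", seed = 1)
  expect_identical(a$events, b$events)
  c <- build_schedule("2D-P", seed = 2)
  expect_false(identical(a$events$side, c$events$side))
})

test_that("expected_direction applies the task rules", {
  expect_equal(expected_direction("2D-A", "right"), "left")
  expect_equal(expected_direction("2D-P", "left"), "left")
  expect_equal(expected_direction("SO-P", "right"), "right")
  expect_equal(expected_direction("VM-A", c("left", "right")),
               c("right", "left"))
  expect_error(expected_direction("2D-G", "left"), "no expected")
  expect_error(expected_direction("EC", "left"), "no expected")
})

test_that("baselines without a visual schedule are rejected", {
  expect_error(build_schedule("EO", seed = 1), "no visual stimulus")
  expect_error(build_schedule("EC", seed = 1), "no visual stimulus")
})

test_that("schedule JSON and CSV round-trips preserve the event log", {
  sch <- build_schedule("VM-P", seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_schedule_json(sch, path)
  back <- read_schedule_json(path)
  expect_equal(back$events, sch$events)
  expect_equal(back$n_practice, sch$n_practice)
  expect_equal(back$cycle_duration, sch$cycle_duration)
  expect_equal(back$condition$name, "VM-P")

  csv <- withr::local_tempfile(fileext = ".csv")
  write_schedule_csv(sch, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), nrow(sch$events))
  expect_true(all(c("t_onset", "frame_kind", "side", "eccentricity",
                    "symbol", "is_practice") %in% names(df)))
})

test_that("gaze-task schedules carry fixation frames only", {
  sch <- build_schedule("2D-G", seed = 1)
  expect_true(all(sch$events$frame_kind == "central_fixation"))
  expect_equal(nrow(response_events(sch)), 0)
})
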