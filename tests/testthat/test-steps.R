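test_that("step detection applies the duration and base-of-support rules", {
  fs <- 1000
  n <- 2000
  left <- plate_with_step(n, fs, "left", base = c(ap = 0, ml = -60))
  # 60 ms in the air, 50 mm AP landing offset -> one step
  right <- plate_with_step(n, fs, "right", air_from = 500, air_to = 560,
                           offset = c(ap = 50, ml = 0))
  steps <- detect_steps(left, right)
  expect_length(steps, 1L)
  expect_identical(steps[[1]]$foot, "right")
  expect_equal(steps[[1]]$duration_s, 0.06)
  expect_equal(unname(steps[[1]]$landing_offset[["ap"]]), 50)

  # 40 ms: below the 50 ms rule
  right2 <- plate_with_step(n, fs, "right", air_from = 500, air_to = 540,
                            offset = c(ap = 50, ml = 0))
  expect_length(detect_steps(left, right2), 0L)

  # 60 ms but 2 mm offset: a weight shift, not a step
  right3 <- plate_with_step(n, fs, "right", air_from = 500, air_to = 560,
                            offset = c(ap = 2, ml = 0))
  expect_length(detect_steps(left, right3), 0L)
})

test_that("the 50 ms boundary is exact at both sampling rates", {
  # 1000 Hz: 50 samples = 50 ms detected, 49 samples not
  for (cs in list(list(fs = 1000, yes = 50, no = 49),
                    list(fs = 120, yes = 6, no = 5))) {
    n <- round(4 * cs$fs)
    a0 <- round(n / 2)
    left <- plate_with_step(n, cs$fs, "left", base = c(ap = 0, ml = -60))
    ryes <- plate_with_step(n, cs$fs, "right", air_from = a0,
                            air_to = a0 + cs$yes,
                            offset = c(ap = 60, ml = 0))
    rno <- plate_with_step(n, cs$fs, "right", air_from = a0,
                           air_to = a0 + cs$no,
                           offset = c(ap = 60, ml = 0))
    expect_length(detect_steps(left, ryes), 1L)
    expect_length(detect_steps(left, rno), 0L)
  }
})

test_that("detection is symmetric in the stepping foot and rejects double gaps", {
  fs <- 120
  n <- 600
  quiet <- plate_with_step(n, fs, "left", base = c(ap = 0, ml = -60))
  stepping_r <- plate_with_step(n, fs, "right", air_from = 200, air_to = 210,
                                offset = c(ap = 0, ml = 40))
  s1 <- detect_steps(quiet, stepping_r)
  # mirror: left foot steps instead
  stepping_l <- plate_with_step(n, fs, "left", air_from = 200, air_to = 210,
                                offset = c(ap = 0, ml = -40),
                                base = c(ap = 0, ml = -60))
  quiet_r <- plate_with_step(n, fs, "right", base = c(ap = 0, ml = 60))
  s2 <- detect_steps(stepping_l, quiet_r)
  expect_length(s1, 1L)
  expect_length(s2, 1L)
  expect_identical(s1[[1]]$foot, "right")
  expect_identical(s2[[1]]$foot, "left")
  expect_equal(s1[[1]]$duration_s, s2[[1]]$duration_s)

  both_l <- plate_with_step(n, fs, "left", air_from = 200, air_to = 210)
  both_r <- plate_with_step(n, fs, "right", air_from = 205, air_to = 215)
  expect_error(detect_steps(both_l, both_r), "signal gap")
})

test_that("chatter within the merge gap joins one unloading interval", {
  fs <- 1000
  n <- 2000
  left <- plate_with_step(n, fs, "left", base = c(ap = 0, ml = -60))
  # two 30 ms air intervals separated by a 10 ms contact blip: merged, 70 ms
  fz <- rep(350, n); ap <- rep(0, n); ml <- rep(60, n)
  fz[500:529] <- 0; fz[540:569] <- 0
  ap[570:n] <- 55
  right <- plate_signal("right", fz, ml, ap, fs)
  steps <- detect_steps(left, right)
  expect_length(steps, 1L)
  expect_gte(steps[[1]]$duration_s, 0.06)
})

test_that("strategy classification and total displacement follow the step list", {
  expect_identical(classify_strategy(list()), "in_place")
  one <- list(structure(list(foot = "left", start_s = 1, end_s = 1.1,
                             duration_s = 0.1,
                             landing_offset = c(ap = 30, ml = 40)),
                        class = "step_event"))
  expect_identical(classify_strategy(one), "single_step")
  expect_equal(step_total_displacement(one), 50)
  three <- c(one, one, one)
  expect_identical(classify_strategy(three), "multiple_steps")
  two <- c(one, list(structure(list(foot = "right", start_s = 2, end_s = 2.1,
                                    duration_s = 0.1,
                                    landing_offset = c(ap = 0, ml = 50)),
                               class = "step_event")))
  expect_equal(step_total_displacement(two), 100)
  expect_equal(step_total_displacement(list()), 0)
  sa <- analyze_steps(list())
  expect_identical(sa$strategy, "in_place")
  expect_equal(sa$total_displacement, 0)
})
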