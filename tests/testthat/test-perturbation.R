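test_that("velocity envelope tracks peaks of a rectified sinusoid", {
  fs <- 500
  t <- (0:(6 * fs)) / fs
  A <- 8
  v <- structure(list(v = A * abs(sin(2 * pi * 1 * t)), fs = fs),
                 class = "velocity_series")
  env <- velocity_envelope(v)
  # away from the edges the peak-interpolated envelope sits near A
  core <- env[(fs):(5 * fs)]
  expect_gt(min(core), 0.95 * A * 0.95)  # low-pass shaves harmonics slightly
  expect_lt(max(core), 1.05 * A)
  # constant signal -> constant envelope
  vc <- structure(list(v = rep(3, 100), fs = 120), class = "velocity_series")
  expect_equal(velocity_envelope(vc), rep(3, 100), tolerance = 1e-6)
  # positive homogeneity
  v3 <- v; v3$v <- 3 * v$v
  expect_equal(velocity_envelope(v3), 3 * env, tolerance = 1e-8)
})

test_that("segmentation clips 9.5 s around onset and discards truncated windows", {
  fs <- 120
  set.seed(13)
  ap <- rnorm(60 * fs, sd = 2); ml <- rnorm(60 * fs, sd = 2)
  ev <- data.frame(onset_s = 20, type = "trans_fwd")
  trial <- trial_from_path(ap, ml, fs, events = ev)
  seg <- segment_perturbation(trial, trial$events[1, ])
  expect_false(seg$discarded)
  expect_equal(length(seg$traj$ap), 1140)    # 9.5 s x 120 Hz
  expect_equal(seg$onset_idx, 601L)          # 5 s of pre-window
  # displacement is referenced to the pre-window mean: AP deviations
  # average to ~0 there
  pre_ap <- seg$traj$ap[seg$pre_idx]
  expect_equal(mean(pre_ap - seg$d$reference[["ap"]]), 0, tolerance = 1e-10)

  ev2 <- data.frame(onset_s = 3, type = "tilt_bwd")
  trial2 <- trial_from_path(ap, ml, fs, events = ev2)
  seg2 <- segment_perturbation(trial2, trial2$events[1, ])
  expect_true(seg2$discarded)
  expect_identical(seg2$discard_reason, "technical")
})

test_that("envelope recovery finds the constructed instant and censors", {
  fs <- 120
  pre <- rep(1, 5 * fs)
  t_post <- (0:(4.5 * fs - 1)) / fs
  # linear decay hits the flat baseline exactly at t = 1.0 s
  post <- 1 + 9 * pmax(0, 1 - t_post)
  env <- c(pre, post)
  r <- envelope_recovery(env, fs, onset_idx = length(pre) + 1L,
                         pre_idx = seq_along(pre))
  expect_false(r$censored)
  expect_equal(r$recovery_s, 1.0, tolerance = 1.5 / fs)
  # never decays -> censored at the window end
  env2 <- c(pre, rep(10, length(post)))
  r2 <- envelope_recovery(env2, fs, length(pre) + 1L, seq_along(pre))
  expect_true(r2$censored)
  expect_equal(r2$recovery_s, 4.5)
  # uniform gain leaves the recovery instant unchanged
  set.seed(31)
  noise <- 0.3 * abs(smooth_noise(length(env), fs))
  env3 <- env + noise
  r3 <- envelope_recovery(env3, fs, length(pre) + 1L, seq_along(pre))
  r3s <- envelope_recovery(5 * env3, fs, length(pre) + 1L, seq_along(pre))
  expect_equal(r3$recovery_s, r3s$recovery_s)
})

test_that("response metrics report cop_max, recovery velocity and strategy", {
  fs <- 120
  n_pre <- 5 * fs
  t_post <- (0:(4.5 * fs - 1)) / fs
  # single smooth displacement lobe peaking at 140 mm
  ap <- c(rep(0, n_pre), 140 * sin(pi * pmin(t_post / 2, 1))^2 *
            exp(-t_post / 1.5))
  trial <- trial_from_path(ap, rep(0, length(ap)), fs,
                           events = data.frame(onset_s = 5,
                                               type = "trans_fwd"))
  seg <- segment_perturbation(trial, trial$events[1, ])
  rm_ <- response_metrics(seg)
  expect_equal(rm_$cop_max, max(ap), tolerance = 0.02)
  expect_identical(rm_$strategy, "in_place")   # no steps supplied
  expect_identical(rm_$n_steps, 0L)
  expect_gte(rm_$mean_recovery_velocity, 0)

  # mean recovery velocity: constant-rate displacement during recovery
  v_const <- structure(list(v = rep(100, 1140), fs = fs),
                       class = "velocity_series")
  expect_equal(mean_velocity(v_const, c(0, 1)), 100)
})

test_that("pre-perturbation standing sway is computed on the pre-window only", {
  fs <- 120
  set.seed(17)
  # inflate post-onset variance wildly; pre-window stats must not change
  ap <- c(rnorm(5 * fs, sd = 1), rnorm(4.5 * fs, sd = 40))
  ml <- c(rnorm(5 * fs, sd = 1), rnorm(4.5 * fs, sd = 40))
  pad <- function(x) c(x, rep(0, fs))  # headroom after the segment
  trial <- trial_from_path(pad(ap), pad(ml), fs,
                           events = data.frame(onset_s = 5,
                                               type = "tilt_left"))
  seg <- segment_perturbation(trial, trial$events[1, ])
  pre <- pre_perturbation_sway(seg)
  expect_equal(pre$n_samples, 600)
  direct <- ellipse_area_95(cop_trajectory(ap[1:600], ml[1:600], fs))
  expect_equal(pre$ellipse_area, direct, tolerance = 1e-8)

  # constant pre-window -> zero area and velocity
  ap2 <- c(rep(3, 5 * fs), rnorm(4.5 * fs, sd = 10))
  trial2 <- trial_from_path(pad(ap2), pad(rep(-2, length(ap2))), fs,
                            events = data.frame(onset_s = 5,
                                                type = "tilt_left"))
  seg2 <- segment_perturbation(trial2, trial2$events[1, ])
  expect_warning(pre2 <- pre_perturbation_sway(seg2), "degenerate|singular")
  expect_equal(pre2$ellipse_area, 0)
  expect_equal(pre2$mean_velocity, 0)
})
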