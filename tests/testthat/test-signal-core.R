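test_that("combine_plates is a force-weighted mean with single-support limit", {
  n <- 20
  fs <- 120
  # symmetric loading, mirrored feet -> midline
  left <- plate_signal("left", rep(400, n), rep(-100, n), rep(0, n), fs)
  right <- plate_signal("right", rep(400, n), rep(100, n), rep(0, n), fs)
  traj <- combine_plates(left, right)
  expect_equal(traj$ml, rep(0, n))
  expect_equal(traj$ap, rep(0, n))

  # asymmetric loading: (600*(-100) + 200*100)/800 = -50
  left <- plate_signal("left", rep(600, n), rep(-100, n), rep(10, n), fs)
  right <- plate_signal("right", rep(200, n), rep(100, n), rep(10, n), fs)
  traj <- combine_plates(left, right)
  expect_equal(traj$ml, rep(-50, n))
  expect_equal(traj$ap, rep(10, n))

  # single support: unloaded plate (even with NA CoP) is ignored
  right0 <- plate_signal("right", rep(0, n), rep(NA_real_, n),
                         rep(NA_real_, n), fs)
  left1 <- plate_signal("left", rep(700, n), rep(-80, n), rep(5, n), fs)
  traj <- combine_plates(left1, right0)
  expect_equal(traj$ml, rep(-80, n))
  expect_equal(traj$ap, rep(5, n))
})

test_that("combine_plates is invariant under plate exchange and rejects gaps", {
  set.seed(11)
  n <- 200
  mk <- function(id) plate_signal(id, runif(n, 200, 600),
                                  rnorm(n, ifelse(id == "left", -50, 50), 5),
                                  rnorm(n, 0, 5), 120)
  l <- mk("left"); r <- mk("right")
  t1 <- combine_plates(l, r)
  # relabel the same data
  l2 <- plate_signal("right", l$fz, l$cop_x, l$cop_y, l$fs)
  r2 <- plate_signal("left", r$fz, r$cop_x, r$cop_y, r$fs)
  t2 <- combine_plates(r2, l2)
  expect_equal(t1$ap, t2$ap)
  expect_equal(t1$ml, t2$ml)

  fz <- rep(300, 10); fz[4] <- 0
  a <- plate_signal("left", fz, rep(0, 10), rep(0, 10), 120)
  b <- plate_signal("right", fz, rep(0, 10), rep(0, 10), 120)
  expect_error(combine_plates(a, b), "sample 4")
})

test_that("displacement magnitude is the distance equation", {
  traj <- cop_trajectory(ap = c(0, 3, 1, 0), ml = c(0, 4, 1, 0), fs = 120)
  d <- displacement_magnitude(traj, reference = c(0, 0))
  expect_equal(d$d, c(0, 5, sqrt(2), 0))

  # constant at reference -> zero series
  traj0 <- cop_trajectory(rep(2, 10), rep(-1, 10), 120)
  expect_equal(displacement_magnitude(traj0, reference = c(2, -1))$d,
               rep(0, 10))
  expect_error(displacement_magnitude(traj, reference = c(NaN, 0)), "finite")
})

test_that("displacement magnitude is rotation invariant about the reference", {
  set.seed(3)
  ap <- rnorm(300); ml <- rnorm(300)
  for (th in c(0.3, 1.2, 2.9)) {
    ap_r <- cos(th) * ap - sin(th) * ml
    ml_r <- sin(th) * ap + cos(th) * ml
    d1 <- displacement_magnitude(cop_trajectory(ap, ml, 120),
                                 reference = c(0, 0))$d
    d2 <- displacement_magnitude(cop_trajectory(ap_r, ml_r, 120),
                                 reference = c(0, 0))$d
    expect_equal(d1, d2)
  }
})

test_that("cop_velocity recovers a linear drift rate at interior samples", {
  fs <- 120
  d <- structure(list(d = 10 * (0:599) / fs, fs = fs,
                      reference = c(ap = 0, ml = 0)),
                 class = "displacement_series")
  v <- cop_velocity(d)
  expect_equal(v$v, rep(10, 600))
  # constant displacement -> zero velocity
  d0 <- structure(list(d = rep(4, 50), fs = fs, reference = c(ap = 0, ml = 0)),
                  class = "displacement_series")
  expect_equal(cop_velocity(d0)$v, rep(0, 50))
  expect_error(cop_velocity(structure(list(d = c(1, 2), fs = fs),
                                      class = "displacement_series")),
               "3 samples")
})

test_that("scalar CoP velocity is not path speed: circular path has ~zero velocity", {
  fs <- 120
  t <- (0:(2 * fs)) / fs
  r <- 10; omega <- 2 * pi
  traj <- cop_trajectory(ap = r * cos(omega * t), ml = r * sin(omega * t), fs)
  d <- displacement_magnitude(traj, reference = c(0, 0))
  v <- cop_velocity(d)
  interior <- v$v[2:(length(v$v) - 1L)]
  expect_lt(max(interior), 0.1)          # derivative of constant |d| = r
  # whereas the 2D path speed is r*omega
  ps <- cop_path_speed(traj)
  expect_equal(median(ps$v), r * omega, tolerance = 0.01)
})

test_that("velocity of a time-reversed displacement is the reversed velocity", {
  set.seed(7)
  d <- structure(list(d = abs(cumsum(rnorm(100))), fs = 120,
                      reference = c(ap = 0, ml = 0)),
                 class = "displacement_series")
  dr <- d; dr$d <- rev(d$d)
  expect_equal(cop_velocity(dr)$v, rev(cop_velocity(d)$v))
})

test_that("trial CSVs round-trip and malformed files raise typed errors", {
  set.seed(21)
  n <- 3600; fs <- 120
  p <- plates_from_path(rnorm(n), rnorm(n), fs)
  trial <- trial_record("P01", "PD", "EC_DT", "sway", p$left, p$right)
  path <- file.path(tempdir(), "trial_rt.csv")
  write_trial(trial, path)
  back <- read_trial(path)
  expect_equal(trial_duration(back), 30)
  expect_identical(back$participant_id, "P01")
  expect_identical(back$group, "PD")
  expect_identical(back$condition, "EC_DT")
  expect_equal(back$left$fz, trial$left$fz, tolerance = 1e-8)
  expect_equal(back$right$cop_y, trial$right$cop_y, tolerance = 1e-8)

  # negative force -> parse error naming the row
  lines <- readLines(path)
  bad <- sub("^([0-9.]+),[0-9.eE+-]+", "\\1,-5", lines[7])
  writeLines(c(lines[1:6], bad, lines[-(1:7)]), path)
  expect_error(read_trial(path), "negative fz_L at row 1")

  # non-monotonic time column
  write_trial(trial, path)
  lines <- readLines(path)
  lines[c(8, 9)] <- lines[c(9, 8)]
  writeLines(lines, path)
  expect_error(read_trial(path), "non-monotonic")
})
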