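# Deterministic fixture builders shared across test files.

# two constant-force plates whose weighted combination equals the given
# AP/ML path exactly (equal loading, zero stance offset)
plates_from_path <- function(ap, ml, fs = 120, fz = 350) {
  n <- length(ap)
  list(
    left = plate_signal("left", rep(fz, n), ml, ap, fs),
    right = plate_signal("right", rep(fz, n), ml, ap, fs)
  )
}

# a perturbation trial whose combined CoP follows the given path
trial_from_path <- function(ap, ml, fs = 120, events = NULL,
                            kind = "perturbation") {
  p <- plates_from_path(ap, ml, fs)
  trial_record("T01", "control", "EO_NoDT", kind, p$left, p$right,
               events = events)
}

# constant-force plate with an unloading window [air_from, air_to) (sample
# indices) and a CoP jump of `offset` (ap, ml) from reloading onward
plate_with_step <- function(n, fs, id = "right", fz = 350,
                            air_from = NULL, air_to = NULL,
                            offset = c(ap = 0, ml = 0),
                            base = c(ap = 0, ml = 60)) {
  fzv <- rep(fz, n)
  ap <- rep(base[["ap"]], n)
  ml <- rep(base[["ml"]], n)
  if (!is.null(air_from)) {
    idx <- air_from:(air_to - 1L)
    fzv[idx] <- 0
    ap[idx] <- NA_real_
    ml[idx] <- NA_real_
    after <- seq(air_to, n)
    ap[after] <- ap[after] + offset[["ap"]]
    ml[after] <- ml[after] + offset[["ml"]]
  }
  plate_signal(id, fzv, ml, ap, fs)
}

# smooth (band-limited) unit-variance noise for envelope tests
smooth_noise <- function(n, fs, corner_hz = 2) {
  x <- stats::rnorm(n)
  bf <- signal::butter(2, corner_hz / (fs / 2), type = "low")
  y <- signal::filtfilt(bf, x)
  y / stats::sd(y)
}
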