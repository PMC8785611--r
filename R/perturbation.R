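#' Peak envelope of an absolute velocity signal
#'
#' The envelope is a piecewise-linear interpolation through the successive
#' local maxima of the velocity signal after a zero-phase low-pass (2nd
#' order Butterworth applied forward and backward) at `lowpass_hz`. The
#' first and last samples are included as anchors so the envelope is
#' defined at every sample. A constant signal has no interior maxima and
#' returns itself. The envelope tracks local peaks; it is not guaranteed to
#' lie above every raw sample (the low-pass removes sub-sample spikes), but
#' it is non-negative and positively homogeneous
#' (`envelope(a * v) = a * envelope(v)` for `a > 0`).
#'
#' @param v A `velocity_series` (length >= 5).
#' @param lowpass_hz Low-pass corner frequency (Hz) applied before peak
#'   picking; skipped when `>= fs/2`.
#' @return Numeric envelope series, same length as `v$v`.
#' @export
velocity_envelope <- function(v, lowpass_hz = 10) {
  stopifnot(inherits(v, "velocity_series"))
  x <- v$v
  n <- length(x)
  if (n < 5L) stop("velocity_envelope: need at least 5 samples", call. = FALSE)
  if (lowpass_hz < v$fs / 2) {
    bf <- signal::butter(2, lowpass_hz / (v$fs / 2), type = "low")
    # odd-reflection padding suppresses filtfilt edge transients
    np <- min(n - 1L, max(1L, round(3 * v$fs / lowpass_hz)))
    xp <- c(2 * x[1L] - x[(np + 1L):2],
            x,
            2 * x[n] - x[(n - 1L):(n - np)])
    xp <- signal::filtfilt(bf, xp)
    x <- xp[(np + 1L):(np + n)]
  }
  x <- pmax(x, 0)
  # interior local maxima (plateau-tolerant: first sample of a flat top)
  left_ok <- c(FALSE, diff(x) > 0)
  right_ok <- c(x[-n] >= x[-1L], FALSE)
  pk <- which(left_ok & right_ok)
  anchors <- unique(c(1L, pk, n))
  if (length(anchors) < 2L) return(rep(x[1L], n))
  env <- stats::approx(anchors, x[anchors], xout = seq_len(n))$y
  pmax(env, 0)
}

#' Cut one perturbation response segment out of a trial
#'
#' Clips the combined CoP trajectory to `[onset - pre_s, onset + post_s]`
#' (default 5 s before to 4.5 s after onset), references the displacement
#' to the mean CoP of the pre-onset window, and attaches the velocity
#' signal and its peak envelope. A segment whose window is truncated by the
#' trial bounds is returned flagged `discarded` with reason `"technical"`
#' and must be excluded from aggregation.
#'
#' @param trial A perturbation `trial_record`.
#' @param event One-row data frame (or list) with `onset_s` and `type`.
#' @param pre_s,post_s Window extent around onset (s).
#' @param lowpass_hz Envelope low-pass corner (Hz), see
#'   [velocity_envelope()].
#' @return A `perturbation_segment`: `event`, `traj`, `d`, `v`, `envelope`,
#'   `onset_idx` (first sample at/after onset, 1-based within the segment),
#'   `pre_idx` (pre-window samples), `discarded`, `discard_reason`.
#' @export
segment_perturbation <- function(trial, event, pre_s = 5, post_s = 4.5,
                                 lowpass_hz = 10) {
  stopifnot(inherits(trial, "trial_record"))
  onset <- as.numeric(event$onset_s)
  dur <- trial_duration(trial)
  if (onset - pre_s < -1e-9 || onset + post_s > dur + 1e-9) {
    return(structure(
      list(event = event, traj = NULL, d = NULL, v = NULL, envelope = NULL,
           onset_idx = NA_integer_, pre_idx = integer(0),
           discarded = TRUE, discard_reason = "technical"),
      class = "perturbation_segment"
    ))
  }
  traj <- combine_plates(trial$left, trial$right)
  seg <- clip_trajectory(traj, onset - pre_s, onset + post_s)
  t <- seg$t0 + (seq_along(seg$ap) - 1L) / seg$fs
  pre_idx <- which(t < onset - 1e-9)
  onset_idx <- pre_idx[length(pre_idx)] + 1L
  ref <- c(ap = mean(seg$ap[pre_idx]), ml = mean(seg$ml[pre_idx]))
  d <- displacement_magnitude(seg, reference = ref)
  v <- cop_velocity(d)
  env <- velocity_envelope(v, lowpass_hz = lowpass_hz)
  structure(
    list(event = event, traj = seg, d = d, v = v, envelope = env,
         onset_idx = onset_idx, pre_idx = pre_idx,
         discarded = FALSE, discard_reason = NA_character_),
    class = "perturbation_segment"
  )
}

#' @export
print.perturbation_segment <- function(x, ...) {
  if (x$discarded) {
    cat(sprintf("<perturbation_segment %s @ %.2f s: DISCARDED (%s)>\n",
                x$event$type, x$event$onset_s, x$discard_reason))
  } else {
    cat(sprintf("<perturbation_segment %s @ %.2f s: %d samples @ %g Hz>\n",
                x$event$type, x$event$onset_s, length(x$traj$ap), x$traj$fs))
  }
  invisible(x)
}

#' Recovery instant from an envelope series (low-level)
#'
#' Steady state is operationalized as a band on the velocity envelope:
#' `band = mean + band_k * sd` of the envelope over the pre-onset window.
#' The recovery instant is the first post-onset time at which the envelope
#' stays at or below the band continuously for at least `dwell_s`. If the
#' envelope never dwells inside the band before the segment ends, the
#' recovery time is censored at the post-onset window length.
#'
#' @param env Numeric envelope series.
#' @param fs Sampling rate (Hz).
#' @param onset_idx 1-based index of the first post-onset sample.
#' @param pre_idx Indices of the pre-onset baseline window.
#' @param band_k Multiplier on the baseline envelope SD (default 2).
#' @param dwell_s Required continuous dwell inside the band (s, default 0.5).
#' @return List: `recovery_s` (time from onset), `censored` (logical),
#'   `band` (threshold value).
#' @export
envelope_recovery <- function(env, fs, onset_idx, pre_idx,
                              band_k = 2, dwell_s = 0.5) {
  base <- env[pre_idx]
  band <- mean(base) + band_k * stats::sd(base)
  post <- env[onset_idx:length(env)]
  max_s <- length(post) / fs
  inside <- post <= band + 1e-12
  dwell_n <- max(1L, ceiling(dwell_s * fs - 1e-9))
  # first index starting a run of >= dwell_n consecutive inside samples
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= dwell_n)
  if (length(ok) == 0L) {
    return(list(recovery_s = max_s, censored = TRUE, band = band))
  }
  list(recovery_s = (starts[ok[1L]] - 1L) / fs, censored = FALSE, band = band)
}

#' Recovery time of a perturbation segment
#'
#' Applies [envelope_recovery()] to the segment's velocity envelope: the
#' baseline band is `mean + band_k * sd` of the envelope over the 5 s
#' pre-onset window, and recovery is the first post-onset instant where the
#' envelope dwells inside the band for `dwell_s`. Scaling the whole
#' velocity signal scales baseline and response together, so the result is
#' invariant under uniform gain.
#'
#' @param seg A `perturbation_segment`.
#' @inheritParams envelope_recovery
#' @return List: `recovery_s`, `censored`, `band`.
#' @export
recovery_time <- function(seg, band_k = 2, dwell_s = 0.5) {
  stopifnot(inherits(seg, "perturbation_segment"))
  if (seg$discarded) stop("recovery_time: segment is discarded", call. = FALSE)
  envelope_recovery(seg$envelope, seg$v$fs, seg$onset_idx, seg$pre_idx,
                    band_k = band_k, dwell_s = dwell_s)
}

#' Full outcome set for one perturbation response
#'
#' Combines the segment-level dynamic outcomes with the step analysis:
#' recovery time (censored at 4.5 s when the envelope never settles),
#' maximal post-onset CoP displacement (`cop_max`, measured from the
#' pre-onset mean), mean absolute velocity from onset to the recovery
#' instant, and the stepping strategy fields.
#'
#' @param seg A `perturbation_segment`.
#' @param steps A `step_analysis` for the same window (see
#'   [analyze_steps()]); `NULL` for an in-place response.
#' @inheritParams envelope_recovery
#' @return A `response_metrics` list.
#' @export
response_metrics <- function(seg, steps = NULL, band_k = 2, dwell_s = 0.5) {
  stopifnot(inherits(seg, "perturbation_segment"))
  if (seg$discarded) {
    return(structure(
      list(recovery_time = NA_real_, censored = NA, cop_max = NA_real_,
           mean_recovery_velocity = NA_real_, strategy = NA_character_,
           n_steps = NA_integer_, step_total_displacement = NA_real_,
           discarded = TRUE, discard_reason = seg$discard_reason),
      class = "response_metrics"
    ))
  }
  rec <- recovery_time(seg, band_k = band_k, dwell_s = dwell_s)
  n <- length(seg$d$d)
  post <- seg$onset_idx:n
  cop_max <- max(seg$d$d[post])
  rec_end <- min(n, seg$onset_idx + max(1L, round(rec$recovery_s * seg$v$fs)))
  mean_rec_v <- mean(seg$v$v[seg$onset_idx:rec_end])
  if (is.null(steps)) steps <- analyze_steps(list())
  structure(
    list(recovery_time = rec$recovery_s, censored = rec$censored,
         cop_max = cop_max, mean_recovery_velocity = mean_rec_v,
         strategy = steps$strategy, n_steps = length(steps$steps),
         step_total_displacement = steps$total_displacement,
         discarded = FALSE, discard_reason = NA_character_),
    class = "response_metrics"
  )
}

#' Static sway outcomes of the pre-perturbation standing window
#'
#' The 5 s of quiet standing before each perturbation are analyzed like a
#' (short) sway trial: 95% ellipse area and mean velocity on the pre-onset
#' window only, referenced to that window's mean CoP.
#'
#' @param seg A `perturbation_segment` with a full pre-window.
#' @return A `sway_metrics`, or `NULL` for a discarded segment.
#' @export
pre_perturbation_sway <- function(seg) {
  stopifnot(inherits(seg, "perturbation_segment"))
  if (seg$discarded) return(NULL)
  pre <- cop_trajectory(seg$traj$ap[seg$pre_idx], seg$traj$ml[seg$pre_idx],
                        seg$traj$fs, t0 = seg$traj$t0)
  win <- c(0, length(seg$pre_idx) / seg$traj$fs)
  sway_metrics_from_traj(pre, win)
}
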