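#' Construct a single force-plate signal
#'
#' Holds one plate's sampled vertical force and CoP coordinates over a trial.
#' Coordinates follow the package convention: `cop_y` is anterior-posterior
#' (AP, positive forward), `cop_x` is medial-lateral (ML, positive rightward),
#' both in millimetres. CoP coordinates may be `NA` at samples where the
#' plate is unloaded (`fz == 0`): an unloaded plate reports no pressure point.
#'
#' @param plate_id "left" or "right".
#' @param fz Vertical force series (N), non-negative.
#' @param cop_x ML coordinate series (mm).
#' @param cop_y AP coordinate series (mm).
#' @param fs Sampling rate (Hz), positive.
#' @return A `plate_signal` object.
#' @export
plate_signal <- function(plate_id, fz, cop_x, cop_y, fs) {
  plate_id <- match.arg(plate_id, c("left", "right"))
  n <- length(fz)
  if (length(cop_x) != n || length(cop_y) != n) {
    stop("plate_signal: fz, cop_x, cop_y must have equal length", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("plate_signal: fs must be a single positive number", call. = FALSE)
  }
  if (anyNA(fz) || any(!is.finite(fz))) {
    stop("plate_signal: fz must be finite everywhere", call. = FALSE)
  }
  if (any(fz < 0)) {
    stop("plate_signal: negative vertical force at sample ",
         which(fz < 0)[1L], call. = FALSE)
  }
  loaded <- fz > 0
  if (any(loaded & (!is.finite(cop_x) | !is.finite(cop_y)))) {
    stop("plate_signal: CoP must be finite wherever fz > 0 (first bad sample ",
         which(loaded & (!is.finite(cop_x) | !is.finite(cop_y)))[1L], ")",
         call. = FALSE)
  }
  structure(
    list(plate_id = plate_id, fz = as.numeric(fz),
         cop_x = as.numeric(cop_x), cop_y = as.numeric(cop_y),
         fs = as.numeric(fs)),
    class = "plate_signal"
  )
}

#' @export
print.plate_signal <- function(x, ...) {
  cat(sprintf("<plate_signal %s: %d samples @ %g Hz, fz %.0f-%.0f N>\n",
              x$plate_id, length(x$fz), x$fs, min(x$fz), max(x$fz)))
  invisible(x)
}

#' Construct a combined CoP trajectory
#'
#' @param ap Anterior-posterior CoP series (mm).
#' @param ml Medial-lateral CoP series (mm).
#' @param fs Sampling rate (Hz).
#' @param t0 Trial-relative start time of the first sample (s).
#' @return A `cop_trajectory` object.
#' @export
cop_trajectory <- function(ap, ml, fs, t0 = 0) {
  if (length(ap) != length(ml)) {
    stop("cop_trajectory: ap and ml must have equal length", call. = FALSE)
  }
  if (any(!is.finite(ap)) || any(!is.finite(ml))) {
    stop("cop_trajectory: non-finite CoP value", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("cop_trajectory: fs must be positive", call. = FALSE)
  }
  structure(list(ap = as.numeric(ap), ml = as.numeric(ml),
                 fs = as.numeric(fs), t0 = as.numeric(t0)),
            class = "cop_trajectory")
}

#' @export
print.cop_trajectory <- function(x, ...) {
  cat(sprintf("<cop_trajectory: %d samples @ %g Hz (%.1f s), t0 = %g s>\n",
              length(x$ap), x$fs, length(x$ap) / x$fs, x$t0))
  invisible(x)
}

#' Combine two force plates into one weighted CoP trajectory
#'
#' Per-sample vertical-force weighting:
#' `ap = (fz_L * y_L + fz_R * y_R) / (fz_L + fz_R)`, likewise for ML.
#' When one plate carries no load (force at or below `zero_threshold`, e.g.
#' the foot is in the air during a compensatory step), the combined CoP is
#' the loaded plate's CoP. Both plates simultaneously unloaded is physically
#' impossible in a standing protocol and raises an error.
#'
#' @param left,right `plate_signal` objects of equal length and rate.
#' @param zero_threshold Force (N) at or below which a plate counts as
#'   unloaded. Default 0 (weighting already vanishes smoothly); raise it for
#'   noisy plates.
#' @return A `cop_trajectory`.
#' @export
combine_plates <- function(left, right, zero_threshold = 0) {
  stopifnot(inherits(left, "plate_signal"), inherits(right, "plate_signal"))
  n <- length(left$fz)
  if (length(right$fz) != n) {
    stop("combine_plates: plates differ in length", call. = FALSE)
  }
  if (!isTRUE(all.equal(left$fs, right$fs))) {
    stop("combine_plates: plates differ in sampling rate", call. = FALSE)
  }
  fl <- left$fz
  fr <- right$fz
  l_off <- fl <= zero_threshold
  r_off <- fr <= zero_threshold
  if (any(l_off & r_off)) {
    stop("combine_plates: both plates unloaded at sample ",
         which(l_off & r_off)[1L], " (signal gap)", call. = FALSE)
  }
  wl <- ifelse(l_off, 0, fl)
  wr <- ifelse(r_off, 0, fr)
  tot <- wl + wr
  # NA CoP on an unloaded plate must not poison the weighted mean
  xl <- ifelse(wl > 0, left$cop_x, 0)
  yl <- ifelse(wl > 0, left$cop_y, 0)
  xr <- ifelse(wr > 0, right$cop_x, 0)
  yr <- ifelse(wr > 0, right$cop_y, 0)
  ml <- (wl * xl + wr * xr) / tot
  ap <- (wl * yl + wr * yr) / tot
  cop_trajectory(ap = ap, ml = ml, fs = left$fs)
}

#' Scalar CoP displacement magnitude (distance equation)
#'
#' Euclidean distance of each trajectory sample from a reference point:
#' `d_i = sqrt((ap_i - ap0)^2 + (ml_i - ml0)^2)`. The default reference is
#' the trajectory's mean position, which makes `d` stationary around zero
#' mean offset under quiet stance; perturbation segments use the
#' pre-perturbation window mean instead (see [segment_perturbation()]).
#'
#' @param traj A `cop_trajectory`.
#' @param reference Numeric `c(ap, ml)` reference point (mm), or `NULL` for
#'   the trajectory mean.
#' @return A `displacement_series` with fields `d`, `fs`, `reference`.
#' @export
displacement_magnitude <- function(traj, reference = NULL) {
  stopifnot(inherits(traj, "cop_trajectory"))
  if (is.null(reference)) {
    reference <- c(ap = mean(traj$ap), ml = mean(traj$ml))
  } else {
    reference <- c(ap = as.numeric(reference[[1L]]),
                   ml = as.numeric(reference[[2L]]))
  }
  if (any(!is.finite(reference))) {
    stop("displacement_magnitude: reference must be finite", call. = FALSE)
  }
  d <- sqrt((traj$ap - reference[["ap"]])^2 + (traj$ml - reference[["ml"]])^2)
  structure(list(d = d, fs = traj$fs, reference = reference),
            class = "displacement_series")
}

#' Absolute CoP velocity from scalar displacement
#'
#' The velocity outcome is defined as the time derivative of the scalar
#' displacement magnitude, not the 2D path speed: a CoP circling the
#' reference at constant radius has (near-)zero velocity under this
#' definition (see [cop_path_speed()] for the alternative). Estimated by a
#' symmetric central difference at interior samples, one-sided differences
#' at the ends, then absolute value; no smoothing at this stage.
#'
#' @param d A `displacement_series` (length >= 3).
#' @return A `velocity_series` with fields `v` (mm/s, non-negative) and
#'   `fs`, same length as `d`.
#' @export
cop_velocity <- function(d) {
  stopifnot(inherits(d, "displacement_series"))
  x <- d$d
  n <- length(x)
  if (n < 3L) {
    stop("cop_velocity: need at least 3 samples", call. = FALSE)
  }
  v <- numeric(n)
  v[1L] <- (x[2L] - x[1L]) * d$fs
  v[n] <- (x[n] - x[n - 1L]) * d$fs
  v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * d$fs / 2
  structure(list(v = abs(v), fs = d$fs), class = "velocity_series")
}

#' 2D CoP path speed
#'
#' The magnitude of the 2D trajectory derivative (speed along the path),
#' provided as the alternative velocity definition; the package's reported
#' outcome is [cop_velocity()].
#'
#' @param traj A `cop_trajectory` (length >= 3).
#' @return A `velocity_series`.
#' @export
cop_path_speed <- function(traj) {
  stopifnot(inherits(traj, "cop_trajectory"))
  n <- length(traj$ap)
  if (n < 3L) {
    stop("cop_path_speed: need at least 3 samples", call. = FALSE)
  }
  diff2 <- function(x) {
    g <- numeric(n)
    g[1L] <- (x[2L] - x[1L])
    g[n] <- (x[n] - x[n - 1L])
    g[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
    g
  }
  vap <- diff2(traj$ap) * traj$fs
  vml <- diff2(traj$ml) * traj$fs
  structure(list(v = sqrt(vap^2 + vml^2), fs = traj$fs),
            class = "velocity_series")
}

# clip a trajectory to [from_s, to_s) in trial time; returns cop_trajectory
clip_trajectory <- function(traj, from_s, to_s) {
  t <- traj$t0 + (seq_along(traj$ap) - 1L) / traj$fs
  keep <- t >= from_s - 1e-9 & t < to_s - 1e-9
  if (!any(keep)) stop("clip_trajectory: empty window", call. = FALSE)
  cop_trajectory(traj$ap[keep], traj$ml[keep], traj$fs, t0 = t[keep][1L])
}
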