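#' Area of the 95% prediction ellipse of a CoP trajectory
#'
#' The ellipse is the covariance-based 95% prediction ellipse: with `S` the
#' 2x2 sample covariance of (AP, ML),
#' `area = pi * q * sqrt(det(S))` where `q = qchisq(0.95, df = 2) = 5.9915`.
#' For bivariate-normal sway this ellipse contains 95% of samples in
#' expectation; the area is invariant under rotation of the (AP, ML) frame
#' and scales quadratically with the coordinates.
#'
#' @param traj A `cop_trajectory` with at least 10 samples.
#' @param conf Coverage probability of the ellipse (default 0.95).
#' @return Area in mm^2. A degenerate trajectory (all points identical)
#'   returns 0 with a warning.
#' @export
ellipse_area_95 <- function(traj, conf = 0.95) {
  stopifnot(inherits(traj, "cop_trajectory"))
  n <- length(traj$ap)
  if (n < 10L) stop("ellipse_area_95: need at least 10 samples", call. = FALSE)
  S <- stats::cov(cbind(traj$ap, traj$ml))
  dt <- det(S)
  if (dt <= 0) {
    if (all(traj$ap == traj$ap[1L]) && all(traj$ml == traj$ml[1L])) {
      warning("ellipse_area_95: degenerate trajectory (all points identical)")
    } else {
      warning("ellipse_area_95: singular covariance (collinear trajectory)")
    }
    return(0)
  }
  pi * stats::qchisq(conf, df = 2) * sqrt(dt)
}

#' Is each trajectory point inside the 95% ellipse?
#'
#' Membership via the squared Mahalanobis distance against the chi-squared
#' quantile that defines the ellipse. Used by the containment checks.
#'
#' @inheritParams ellipse_area_95
#' @return Logical vector, one entry per sample.
#' @export
in_ellipse_95 <- function(traj, conf = 0.95) {
  stopifnot(inherits(traj, "cop_trajectory"))
  X <- cbind(traj$ap, traj$ml)
  S <- stats::cov(X)
  md2 <- stats::mahalanobis(X, colMeans(X), S)
  md2 <= stats::qchisq(conf, df = 2)
}

#' Mean absolute CoP velocity over a time window
#'
#' @param v A `velocity_series`.
#' @param window `c(start_s, end_s)` relative to the start of the series
#'   (half-open), or `NULL` for the whole series.
#' @return Mean velocity (mm/s).
#' @export
mean_velocity <- function(v, window = NULL) {
  stopifnot(inherits(v, "velocity_series"))
  if (is.null(window)) return(mean(v$v))
  t <- (seq_along(v$v) - 1L) / v$fs
  keep <- t >= window[1L] - 1e-9 & t < window[2L] - 1e-9
  if (!any(keep)) stop("mean_velocity: empty window", call. = FALSE)
  mean(v$v[keep])
}

#' Static sway outcomes for a quiet-stance trial
#'
#' Computes the two static outcomes on the middle 20 s of the 30 s trial
#' (samples in `[5 s, 25 s)` by default): the 95% ellipse area of the
#' combined CoP trajectory and the mean absolute CoP velocity, with the
#' displacement referenced to the window's mean CoP. The same window is
#' used for both outcomes.
#'
#' @param trial A sway `trial_record` of at least 30 s.
#' @param window Analysis window `c(start_s, end_s)` in trial time.
#' @return A `sway_metrics` list: `ellipse_area` (mm^2), `mean_velocity`
#'   (mm/s), `window`, `n_samples`, `reference`.
#' @export
sway_metrics <- function(trial, window = c(5, 25)) {
  stopifnot(inherits(trial, "trial_record"))
  if (trial_duration(trial) < (window[2L] - 1e-9)) {
    stop("sway_metrics: trial shorter than the analysis window (",
         round(trial_duration(trial), 2), " s < ", window[2L], " s)",
         call. = FALSE)
  }
  traj <- combine_plates(trial$left, trial$right)
  win <- clip_trajectory(traj, window[1L], window[2L])
  sway_metrics_from_traj(win, window)
}

# shared by sway trials and pre-perturbation windows
sway_metrics_from_traj <- function(win, window) {
  d <- displacement_magnitude(win)          # reference = window mean
  v <- cop_velocity(d)
  structure(
    list(ellipse_area = ellipse_area_95(win),
         mean_velocity = mean(v$v),
         window = window,
         n_samples = length(win$ap),
         reference = d$reference),
    class = "sway_metrics"
  )
}

#' @export
print.sway_metrics <- function(x, ...) {
  cat(sprintf(
    "<sway_metrics: area %.1f mm^2, velocity %.2f mm/s over [%g, %g) s (n = %d)>\n",
    x$ellipse_area, x$mean_velocity, x$window[1L], x$window[2L], x$n_samples))
  invisible(x)
}
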