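#' Detect compensatory steps from single-plate unloading
#'
#' A recovery step is a maximal interval where exactly one plate's vertical
#' force stays at or below `force_threshold` for at least `min_duration_s`
#' (the foot is in the air), and the stepping plate's CoP after reloading
#' differs from its position before unloading by at least `min_offset_mm`
#' (the base of support changed — a pure weight shift does not count).
#' Unloading intervals on the same plate separated by less than
#' `merge_gap_s` are merged first, absorbing contact chatter at touchdown.
#'
#' @param left,right `plate_signal` objects of equal length and rate.
#' @param window `c(start_s, end_s)` in trial time to search, or `NULL` for
#'   the whole trial.
#' @param force_threshold Force (N) at or below which a plate counts as
#'   unloaded; plates never read exactly zero, default 5 N.
#' @param min_duration_s Minimum airborne duration (s), default 0.05 (50 ms).
#' @param merge_gap_s Intervals closer than this are merged (s), default 0.03.
#' @param min_offset_mm Minimum CoP landing offset (mm), default 20.
#' @param offset_window_s Window used to average the plate CoP just before
#'   lift-off and just after touchdown (s), default 0.1.
#' @return List of `step_event`s: `foot`, `start_s`, `end_s`, `duration_s`,
#'   `landing_offset` (`c(ap, ml)` mm).
#' @export
detect_steps <- function(left, right, window = NULL,
                         force_threshold = 5, min_duration_s = 0.05,
                         merge_gap_s = 0.03, min_offset_mm = 20,
                         offset_window_s = 0.1) {
  stopifnot(inherits(left, "plate_signal"), inherits(right, "plate_signal"))
  fs <- left$fs
  n <- length(left$fz)
  t <- (seq_len(n) - 1L) / fs
  idx <- if (is.null(window)) seq_len(n) else {
    which(t >= window[1L] - 1e-9 & t < window[2L] - 1e-9)
  }
  if (length(idx) == 0L) stop("detect_steps: empty window", call. = FALSE)
  l_off <- left$fz[idx] <= force_threshold
  r_off <- right$fz[idx] <= force_threshold
  if (any(l_off & r_off)) {
    stop("detect_steps: both plates unloaded at ",
         round(t[idx][which(l_off & r_off)[1L]], 3),
         " s (signal gap)", call. = FALSE)
  }
  steps <- c(
    unload_events(left, idx, l_off, fs, min_duration_s, merge_gap_s,
                  min_offset_mm, offset_window_s),
    unload_events(right, idx, r_off, fs, min_duration_s, merge_gap_s,
                  min_offset_mm, offset_window_s)
  )
  steps[order(vapply(steps, function(s) s$start_s, numeric(1)))]
}

# maximal unloading runs on one plate -> step events passing both thresholds
unload_events <- function(plate, idx, off, fs, min_duration_s, merge_gap_s,
                          min_offset_mm, offset_window_s) {
  r <- rle(off)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) == 0L) return(list())
  # merge runs separated by < merge_gap_s
  gap_n <- merge_gap_s * fs
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      if (runs[i, 1L] - merged[nrow(merged), 2L] - 1L < gap_n - 1e-9) {
        merged[nrow(merged), 2L] <- runs[i, 2L]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
  }
  out <- list()
  wn <- max(1L, round(offset_window_s * fs))
  n_idx <- length(idx)
  for (i in seq_len(nrow(merged))) {
    a <- merged[i, 1L]; b <- merged[i, 2L]
    dur <- (b - a + 1L) / fs
    if (dur < min_duration_s - 1e-9) next
    pre <- idx[max(1L, a - wn):max(1L, a - 1L)]
    post <- idx[min(n_idx, b + 1L):min(n_idx, b + wn)]
    pre <- pre[plate$fz[pre] > 0]
    post <- post[plate$fz[post] > 0]
    if (length(pre) == 0L || length(post) == 0L) next  # stepped off the plate
    off_ap <- mean(plate$cop_y[post]) - mean(plate$cop_y[pre])
    off_ml <- mean(plate$cop_x[post]) - mean(plate$cop_x[pre])
    if (sqrt(off_ap^2 + off_ml^2) < min_offset_mm) next
    out[[length(out) + 1L]] <- structure(
      list(foot = plate$plate_id,
           start_s = (idx[a] - 1L) / fs,
           end_s = (idx[b] - 1L) / fs + 1 / fs,
           duration_s = dur,
           landing_offset = c(ap = off_ap, ml = off_ml)),
      class = "step_event"
    )
  }
  out
}

#' Classify the balance-recovery strategy from detected steps
#'
#' @param steps List of `step_event`s.
#' @return `"in_place"` (0 steps), `"single_step"` (1) or
#'   `"multiple_steps"` (2+).
#' @export
classify_strategy <- function(steps) {
  n <- length(steps)
  if (n == 0L) "in_place" else if (n == 1L) "single_step" else "multiple_steps"
}

#' Total step displacement (distance equation over landing offsets)
#'
#' Sum over steps of `sqrt(d_ap^2 + d_ml^2)` of the landing offset; 0 for
#' an in-place response.
#'
#' @param steps List of `step_event`s.
#' @return Displacement in mm.
#' @export
step_total_displacement <- function(steps) {
  if (length(steps) == 0L) return(0)
  sum(vapply(steps, function(s) {
    sqrt(sum(s$landing_offset^2))
  }, numeric(1)))
}

#' Bundle detected steps into a strategy summary
#'
#' @param steps List of `step_event`s (possibly empty).
#' @return A `step_analysis`: `steps`, `strategy`, `total_displacement`.
#' @export
analyze_steps <- function(steps) {
  structure(
    list(steps = steps,
         strategy = classify_strategy(steps),
         total_displacement = step_total_displacement(steps)),
    class = "step_analysis"
  )
}
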