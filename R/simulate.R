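#' Default synthetic-cohort generator configuration
#'
#' The generator emulates a two-group force-plate balance study: quiet
#' stance (30 s, eyes open/closed, with/without a serial-subtraction dual
#' task), perturbation trials (8 platform translations/tilts separated by a
#' 5 s return plus a 9-15 s random interval), compensatory stepping, and
#' counting-task tallies. The clinical-group ("PD") phenotype is postural
#' rigidity: smaller sway ellipse, higher CoP velocity, faster recovery,
#' and markedly more multiple-step episodes.
#'
#' Sway is a 2D Ornstein-Uhlenbeck (OU) process (mean-reversion `k` in 1/s,
#' drive `sigma` in mm/sqrt(s); stationary per-axis variance
#' `sigma^2 / (2k)`), band-limited at `bandwidth_hz`, plus white positional
#' jitter (mm) that sets the mean CoP velocity independently of the
#' ellipse area. Perturbations superpose a double-exponential displacement
#' kernel with peak amplitude `amp_*` (mm), rise constant `tau_rise_s` and
#' group-specific recovery constant `tau_recovery_s`. Group parameters are
#' calibrated so control-group outputs sit at the scales typical of healthy
#' adults on this protocol (eyes-open area near 150 mm^2, velocity near
#' 9 mm/s, reference counting rate 17.5/min) with clinical-group ratios of
#' about 0.7 (area), 1.3 (velocity) and 0.76 (recovery time).
#'
#' @param n_pd,n_control Participants per group.
#' @param fs Sampling rate (Hz).
#' @param seed Master seed; all randomness flows from it through named
#'   substreams, so identical configs give bit-identical cohorts.
#' @return A `generator_config` list; override individual entries by
#'   `modifyList()` on the result.
#' @export
default_generator_config <- function(n_pd = 12, n_control = 11, fs = 120,
                                     seed = 1L) {
  structure(list(
    n_pd = n_pd, n_control = n_control, fs = fs, seed = as.integer(seed),
    body_weight_n = 700,
    stance_half_width_mm = 50,
    load_modulation = 0.05,       # slow anti-phase L/R load share wobble
    load_modulation_hz = 0.3,
    force_noise_sd_n = 2,
    bandwidth_hz = 1.2,           # sway band limit (Inf = raw OU)
    sway = list(
      control = list(k = 7.0, sigma = 17, jitter = 0.05),
      PD      = list(k = 8.7, sigma = 17, jitter = 0.16)
    ),
    # between-participant heterogeneity (log-normal multipliers)
    subject_sdlog = c(sigma = 0.10, jitter_control = 0.20, jitter_PD = 0.35,
                      tau = 0.15),
    ec_sigma_factor  = c(control = 1.05, PD = 0.90),
    ec_jitter_factor = c(control = 1.20, PD = 0.90),
    dt_sigma_factor  = c(control = 2.05, PD = 1.95),
    dt_jitter_factor = c(control = 2.50, PD = 1.20),
    # pre-perturbation anticipation inflates sway in perturbation trials
    anticipation_sigma_factor = 2,
    anticipation_jitter_factor = 3,
    perturbation = list(
      n_events = 8,
      amp_translation_mm = 140, amp_tilt_mm = 110,
      tau_rise_s = 0.1, osc_hz = 1.2,
      tau_recovery_s = c(control = 0.8, PD = 0.6),
      first_onset_s = 6, return_s = 5, gap_range_s = c(9, 15),
      tail_s = 6
    ),
    stepping = list(
      p_step = c(control = 0.38, PD = 0.36),
      p_multiple_given_step = c(control = 0.03, PD = 0.60),
      delay_range_s = c(0.3, 0.6),
      duration_range_s = c(0.10, 0.25),
      inter_step_s = 0.45,
      offset_range_mm = c(40, 90),
      extra_steps_max = 3
    ),
    counting = list(
      rate_mean = c(control = 17.5, PD = 11.9), rate_sd = 3.6,
      sway_factor = c(control = 1.137, PD = 1.084),
      pert_factor = c(control = 0.931, PD = 0.815),
      reference_duration_s = 60
    )
  ), class = "generator_config")
}

#' Deterministic substream seed from a master seed and labels
#'
#' Hashes the master seed together with arbitrary labels into a 31-bit
#' integer, so every participant/trial/purpose gets its own reproducible
#' RNG substream.
#'
#' @param master Master seed (integer).
#' @param ... Labels (coerced to character).
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master, ...) {
  lab <- paste(c(as.character(master), vapply(list(...), as.character,
                                              character(1))),
               collapse = "/")
  h <- 0
  for (ch in utf8ToInt(lab)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# exact-discretization OU series, stationary start
ou_series <- function(n, dt, k, sigma) {
  var_st <- sigma^2 / (2 * k)
  a <- exp(-k * dt)
  x1 <- stats::rnorm(1L, 0, sqrt(var_st))
  eps <- stats::rnorm(n - 1L, 0, sqrt(var_st * (1 - a^2)))
  c(x1, as.numeric(stats::filter(eps, a, method = "recursive", init = x1)))
}

lowpass_zerophase <- function(x, fs, fc) {
  if (!is.finite(fc) || fc >= fs / 2) return(x)
  bf <- signal::butter(2, fc / (fs / 2), type = "low")
  signal::filtfilt(bf, x)
}

# 2D band-limited OU + white jitter; returns list(ap, ml)
sway_background <- function(n, fs, k, sigma, jitter, bandwidth_hz) {
  dt <- 1 / fs
  ap <- lowpass_zerophase(ou_series(n, dt, k, sigma), fs, bandwidth_hz)
  ml <- lowpass_zerophase(ou_series(n, dt, k, sigma), fs, bandwidth_hz)
  if (jitter > 0) {
    ap <- ap + stats::rnorm(n, 0, jitter)
    ml <- ml + stats::rnorm(n, 0, jitter)
  }
  list(ap = ap, ml = ml)
}

cond_eyes <- function(condition) sub("_.*$", "", condition)
cond_dt <- function(condition) endsWith(condition, "_DT")

# effective sway parameters for one participant/condition
effective_sway <- function(cfg, group, condition, subject,
                           anticipation = FALSE) {
  p <- cfg$sway[[group]]
  sigma <- p$sigma * subject$sigma_mult
  jitter <- p$jitter * subject$jitter_mult
  if (cond_eyes(condition) == "EC") {
    sigma <- sigma * cfg$ec_sigma_factor[[group]]
    jitter <- jitter * cfg$ec_jitter_factor[[group]]
  }
  if (cond_dt(condition)) {
    sigma <- sigma * cfg$dt_sigma_factor[[group]]
    jitter <- jitter * cfg$dt_jitter_factor[[group]]
  }
  if (anticipation) {
    sigma <- sigma * cfg$anticipation_sigma_factor
    jitter <- jitter * cfg$anticipation_jitter_factor
  }
  list(k = p$k, sigma = sigma, jitter = jitter)
}

default_subject <- function() {
  list(sigma_mult = 1, jitter_mult = 1, tau_mult = 1)
}

# split a combined trajectory into two plate signals, honouring a step
# schedule (list of list(foot, start_s, end_s, offset = c(ap, ml),
# reset_s)); steps unload one plate completely and relocate its CoP.
make_plates <- function(ap, ml, fs, cfg, steps = list()) {
  n <- length(ap)
  t <- (seq_len(n) - 1L) / fs
  W <- cfg$body_weight_n
  s <- cfg$stance_half_width_mm
  share <- 0.5 * (1 + cfg$load_modulation *
                    sin(2 * pi * cfg$load_modulation_hz * t +
                          stats::runif(1, 0, 2 * pi)))
  fz_L <- W * share
  fz_R <- W * (1 - share)
  off_L_ap <- numeric(n); off_L_ml <- numeric(n)
  off_R_ap <- numeric(n); off_R_ml <- numeric(n)
  # a stepping foot's CoP does not track the body swing (the stance foot
  # does the balancing): hold its dynamic component around the air
  # interval, then ramp back, so the landing offset is a genuine
  # base-of-support change rather than leaked body motion
  dyn_ap_L <- ap; dyn_ml_L <- ml
  dyn_ap_R <- ap; dyn_ml_R <- ml
  hold_margin_s <- 0.15; ramp_s <- 0.2
  for (st in steps) {
    air <- t >= st$start_s - 1e-9 & t < st$end_s - 1e-9
    landed <- t >= st$end_s - 1e-9 & t < st$reset_s - 1e-9
    i0 <- max(1L, which(t >= st$start_s - hold_margin_s)[1L])
    hold <- t >= t[i0] - 1e-9 & t < st$end_s + hold_margin_s - 1e-9
    ramp <- t >= st$end_s + hold_margin_s - 1e-9 &
      t < st$end_s + hold_margin_s + ramp_s - 1e-9
    lam <- (t[ramp] - (st$end_s + hold_margin_s)) / ramp_s
    if (st$foot == "left") {
      fz_L[air] <- 0
      dyn_ap_L[hold] <- ap[i0]; dyn_ml_L[hold] <- ml[i0]
      dyn_ap_L[ramp] <- (1 - lam) * ap[i0] + lam * ap[ramp]
      dyn_ml_L[ramp] <- (1 - lam) * ml[i0] + lam * ml[ramp]
      off_L_ap[landed] <- off_L_ap[landed] + st$offset[["ap"]]
      off_L_ml[landed] <- off_L_ml[landed] + st$offset[["ml"]]
    } else {
      fz_R[air] <- 0
      dyn_ap_R[hold] <- ap[i0]; dyn_ml_R[hold] <- ml[i0]
      dyn_ap_R[ramp] <- (1 - lam) * ap[i0] + lam * ap[ramp]
      dyn_ml_R[ramp] <- (1 - lam) * ml[i0] + lam * ml[ramp]
      off_R_ap[landed] <- off_R_ap[landed] + st$offset[["ap"]]
      off_R_ml[landed] <- off_R_ml[landed] + st$offset[["ml"]]
    }
  }
  tot <- fz_L + fz_R
  # stance offsets balance out in the weighted mean; landing offsets do not
  # (the base of support genuinely moved)
  cop_L_ml <- dyn_ml_L - 2 * fz_R / W * s + off_L_ml
  cop_R_ml <- dyn_ml_R + 2 * fz_L / W * s + off_R_ml
  cop_L_ap <- dyn_ap_L + off_L_ap
  cop_R_ap <- dyn_ap_R + off_R_ap
  if (cfg$force_noise_sd_n > 0) {
    fz_L <- pmax(0, fz_L + stats::rnorm(n, 0, cfg$force_noise_sd_n) *
                   (fz_L > 0))
    fz_R <- pmax(0, fz_R + stats::rnorm(n, 0, cfg$force_noise_sd_n) *
                   (fz_R > 0))
  }
  cop_L_ml[fz_L == 0] <- NA_real_; cop_L_ap[fz_L == 0] <- NA_real_
  cop_R_ml[fz_R == 0] <- NA_real_; cop_R_ap[fz_R == 0] <- NA_real_
  list(
    left = plate_signal("left", fz_L, cop_L_ml, cop_L_ap, fs),
    right = plate_signal("right", fz_R, cop_R_ml, cop_R_ap, fs)
  )
}

#' Simulate one quiet-stance (sway) trial
#'
#' @param cfg A `generator_config`.
#' @param group "PD" or "control".
#' @param condition "EO_NoDT", "EO_DT", "EC_NoDT" or "EC_DT".
#' @param duration_s Trial length (s), at least 30.
#' @param seed Substream seed for this trial.
#' @param participant_id Identifier stored in the trial.
#' @param subject Per-participant multiplier list (internal; defaults to
#'   neutral multipliers).
#' @return List: `trial` (a `trial_record`) and `truth` (effective sway
#'   parameters and the stationary per-axis OU variance).
#' @export
simulate_sway <- function(cfg, group, condition, duration_s = 30, seed = 1L,
                          participant_id = "S01",
                          subject = default_subject()) {
  stopifnot(inherits(cfg, "generator_config"))
  if (duration_s < 30) stop("simulate_sway: duration must be >= 30 s",
                            call. = FALSE)
  group <- match.arg(group, c("PD", "control"))
  n <- round(duration_s * cfg$fs)
  eff <- effective_sway(cfg, group, condition, subject)
  with_seed(seed, {
    bg <- sway_background(n, cfg$fs, eff$k, eff$sigma, eff$jitter,
                          cfg$bandwidth_hz)
    plates <- make_plates(bg$ap, bg$ml, cfg$fs, cfg)
    trial <- trial_record(participant_id, group, condition, "sway",
                          plates$left, plates$right)
    list(trial = trial,
         truth = list(k = eff$k, sigma = eff$sigma, jitter = eff$jitter,
                      var_axis = eff$sigma^2 / (2 * eff$k)))
  })
}

# Perturbation displacement kernel: a damped postural oscillation under a
# double-exponential amplitude envelope (rise tau_rise, recovery tau_rec),
# normalized so the displacement peak equals `amp`. The oscillation gives
# the velocity signal the train of decaying peaks seen in real responses,
# so its peak envelope decays like exp(-t/tau_rec) and the recovery
# instant is well defined.
perturbation_kernel <- function(t_rel, amp, tau_rise, tau_rec,
                                osc_hz = 1.2) {
  raw <- function(t) {
    ifelse(t <= 0, 0,
           (exp(-t / tau_rec) - exp(-t / tau_rise)) *
             cos(2 * pi * osc_hz * t))
  }
  grid <- seq(0, 6 * tau_rec, by = tau_rise / 20)
  amp / max(abs(raw(grid))) * raw(t_rel)
}

ptype_direction <- function(type) {
  d <- sub("^(trans|tilt)_", "", type)
  switch(d,
         fwd = c(ap = 1, ml = 0), bwd = c(ap = -1, ml = 0),
         left = c(ap = 0, ml = -1), right = c(ap = 0, ml = 1))
}

# True recovery instant from the noise-free kernel: the segment's own
# detector (envelope -> baseline band -> dwell) applied to a composite in
# which the pre-onset window is the generated sway (it defines the band,
# exactly as the detector will see it) and the post-onset displacement is
# the noise-free kernel alone. The recorded truth is therefore what the
# detector would report in the absence of post-onset sway noise; the
# recovery-consistency property measures how far that noise moves it.
true_recovery_instant <- function(kern_d, bg, onset_idx, pre_idx, fs,
                                  band_k = 2, dwell_s = 0.5,
                                  lowpass_hz = 10) {
  ref <- c(mean(bg$ap[pre_idx]), mean(bg$ml[pre_idx]))
  d_comp <- sqrt((bg$ap - ref[1L])^2 + (bg$ml - ref[2L])^2)
  post <- onset_idx:length(d_comp)
  d_comp[post] <- abs(kern_d[post])
  ds <- structure(list(d = d_comp, fs = fs), class = "displacement_series")
  env <- velocity_envelope(cop_velocity(ds), lowpass_hz = lowpass_hz)
  envelope_recovery(env, fs, onset_idx, pre_idx,
                    band_k = band_k, dwell_s = dwell_s)$recovery_s
}

#' Simulate one perturbation trial
#'
#' Band-limited OU sway (with anticipation inflation) carries, at each
#' perturbation onset, a double-exponential displacement kernel oriented
#' along the perturbation axis. With the configured probability the
#' response includes one or several compensatory steps: one plate unloads
#' completely for 100-250 ms and relands with a 40-90 mm offset, restoring
#' the original stance when the platform returns 5 s after onset.
#' Inter-onset gaps are the 5 s return plus a uniform 9-15 s interval.
#'
#' @inheritParams simulate_sway
#' @param n_events Number of perturbations (default from config; the
#'   protocol uses 8 per trial).
#' @return List: `trial` (a `trial_record` with its event table) and
#'   `truth` (per-event data frame: type, onset, true recovery instant from
#'   the noise-free kernel, injected step count and step displacement).
#' @export
simulate_perturbation_trial <- function(cfg, group, condition = "EO_NoDT",
                                        n_events = NULL, seed = 1L,
                                        participant_id = "S01",
                                        subject = default_subject()) {
  stopifnot(inherits(cfg, "generator_config"))
  group <- match.arg(group, c("PD", "control"))
  pc <- cfg$perturbation
  sc <- cfg$stepping
  if (is.null(n_events)) n_events <- pc$n_events
  if (n_events < 1L) stop("simulate_perturbation_trial: n_events >= 1",
                          call. = FALSE)
  fs <- cfg$fs
  with_seed(seed, {
    gaps <- stats::runif(n_events - 1L, pc$gap_range_s[1L], pc$gap_range_s[2L])
    onsets <- pc$first_onset_s + c(0, cumsum(pc$return_s + gaps))
    types <- sample(perturbation_types(), n_events, replace = n_events > 8L)
    duration <- onsets[n_events] + pc$return_s + pc$tail_s
    n <- round(duration * fs)
    t <- (seq_len(n) - 1L) / fs
    eff <- effective_sway(cfg, group, condition, subject, anticipation = TRUE)
    bg <- sway_background(n, fs, eff$k, eff$sigma, eff$jitter, cfg$bandwidth_hz)
    tau_rec <- pc$tau_recovery_s[[group]] * subject$tau_mult
    ap <- bg$ap; ml <- bg$ml
    steps_sched <- list()
    truth <- vector("list", n_events)
    for (i in seq_len(n_events)) {
      amp <- if (startsWith(types[i], "trans")) pc$amp_translation_mm else
        pc$amp_tilt_mm
      u <- ptype_direction(types[i])
      kern <- perturbation_kernel(t - onsets[i], amp, pc$tau_rise_s, tau_rec,
                                  osc_hz = pc$osc_hz)
      ap <- ap + u[["ap"]] * kern
      ml <- ml + u[["ml"]] * kern
      # injected steps
      ev_steps <- list()
      if (stats::runif(1) < sc$p_step[[group]]) {
        n_steps <- 1L
        if (stats::runif(1) < sc$p_multiple_given_step[[group]]) {
          n_steps <- 1L + sample.int(sc$extra_steps_max, 1L)
        }
        foot <- sample(c("left", "right"), 1L)
        t_cur <- onsets[i] + stats::runif(1, sc$delay_range_s[1L],
                                          sc$delay_range_s[2L])
        for (k in seq_len(n_steps)) {
          dur <- stats::runif(1, sc$duration_range_s[1L],
                              sc$duration_range_s[2L])
          mag <- stats::runif(1, sc$offset_range_mm[1L],
                              sc$offset_range_mm[2L])
          ang <- atan2(u[["ml"]], u[["ap"]]) + stats::rnorm(1, 0, 0.3)
          ev_steps[[k]] <- list(
            foot = foot, start_s = t_cur, end_s = t_cur + dur,
            offset = c(ap = mag * cos(ang), ml = mag * sin(ang)),
            reset_s = onsets[i] + pc$return_s
          )
          foot <- if (foot == "left") "right" else "left"
          t_cur <- t_cur + dur + sc$inter_step_s
        }
      }
      steps_sched <- c(steps_sched, ev_steps)
      # truth uses the event's own segment geometry
      seg_lo <- which(t >= onsets[i] - 5 - 1e-9)[1L]
      seg_hi <- max(which(t < onsets[i] + 4.5 - 1e-9))
      pre_idx_loc <- which(t[seg_lo:seg_hi] < onsets[i] - 1e-9)
      onset_loc <- pre_idx_loc[length(pre_idx_loc)] + 1L
      bg_seg <- list(ap = bg$ap[seg_lo:seg_hi], ml = bg$ml[seg_lo:seg_hi])
      kern_seg <- kern[seg_lo:seg_hi]
      truth[[i]] <- data.frame(
        event = i, type = types[i], onset_s = onsets[i],
        true_recovery_s = true_recovery_instant(kern_seg, bg_seg, onset_loc,
                                                pre_idx_loc, fs),
        n_steps = length(ev_steps),
        step_displacement = if (length(ev_steps)) {
          sum(vapply(ev_steps, function(s) sqrt(sum(s$offset^2)), numeric(1)))
        } else 0,
        stringsAsFactors = FALSE
      )
    }
    plates <- make_plates(ap, ml, fs, cfg, steps_sched)
    events <- data.frame(onset_s = onsets, type = types,
                         stringsAsFactors = FALSE)
    trial <- trial_record(participant_id, group, condition, "perturbation",
                          plates$left, plates$right, events = events)
    list(trial = trial, truth = do.call(rbind, truth))
  })
}

#' Simulate a counting-task record
#'
#' Correct serial-subtraction counts are Poisson with the group- and
#' context-specific rate; each participant carries their own baseline rate
#' (normal across participants, truncated at 3/min).
#'
#' @inheritParams simulate_sway
#' @param context "reference", "sway" or "perturbation".
#' @param duration_s Context duration (s).
#' @param rate_ref Participant baseline rate (counts/min); drawn from the
#'   group distribution when `NULL`.
#' @return A `counting_record`; the realized rate is attached as attribute
#'   `"true_rate"`.
#' @export
simulate_counting <- function(cfg, group, context, duration_s, seed = 1L,
                              rate_ref = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  group <- match.arg(group, c("PD", "control"))
  context <- match.arg(context, c("reference", "sway", "perturbation"))
  cc <- cfg$counting
  with_seed(seed, {
    if (is.null(rate_ref)) {
      rate_ref <- max(3, stats::rnorm(1, cc$rate_mean[[group]], cc$rate_sd))
    }
    rate <- switch(context,
                   reference = rate_ref,
                   sway = rate_ref * cc$sway_factor[[group]],
                   perturbation = rate_ref * cc$pert_factor[[group]])
    counts <- stats::rpois(1L, rate * duration_s / 60)
    rec <- counting_record(counts, duration_s, context)
    attr(rec, "true_rate") <- rate
    rec
  })
}

#' Simulate a full synthetic cohort
#'
#' Per participant: the requested quiet-stance trials (default all four
#' eyes x dual-task conditions), the requested perturbation trials (default
#' with and without dual task), and counting records for the reference
#' baseline, every dual-task sway trial, and every dual-task perturbation
#' trial. Per-participant heterogeneity (sway scale, jitter, recovery time
#' constant, baseline counting rate) is drawn once per participant.
#'
#' @param cfg A `generator_config`.
#' @param sway_conditions Character vector of sway conditions to simulate.
#' @param pert_conditions Character vector of perturbation-trial conditions.
#' @return A `synthetic_cohort` list: `trials` (named list of
#'   `trial_record`), `truth` (named list, keys matching `trials`),
#'   `counting` (tibble of counting records), `participants` (tibble of
#'   per-participant draws), `cfg`.
#' @export
simulate_cohort <- function(cfg = default_generator_config(),
                            sway_conditions = c("EO_NoDT", "EO_DT",
                                                "EC_NoDT", "EC_DT"),
                            pert_conditions = c("EO_NoDT", "EO_DT")) {
  stopifnot(inherits(cfg, "generator_config"))
  ids <- c(sprintf("PD%02d", seq_len(cfg$n_pd)),
           sprintf("C%02d", seq_len(cfg$n_control)))
  groups <- c(rep("PD", cfg$n_pd), rep("control", cfg$n_control))
  trials <- list(); truth <- list()
  counting <- list(); participants <- list()
  for (j in seq_along(ids)) {
    id <- ids[j]; grp <- groups[j]
    sj <- with_seed(substream_seed(cfg$seed, id, "subject"), {
      sdl <- cfg$subject_sdlog
      jit_sdl <- if (grp == "PD") sdl[["jitter_PD"]] else
        sdl[["jitter_control"]]
      list(sigma_mult = stats::rlnorm(1, 0, sdl[["sigma"]]),
           jitter_mult = stats::rlnorm(1, 0, jit_sdl),
           tau_mult = stats::rlnorm(1, 0, sdl[["tau"]]))
    })
    rate_ref <- attr(
      ref_rec <- simulate_counting(cfg, grp, "reference",
                                   cfg$counting$reference_duration_s,
                                   seed = substream_seed(cfg$seed, id, "ref")),
      "true_rate")
    counting[[length(counting) + 1L]] <- tibble::tibble(
      participant_id = id, group = grp, context = "reference",
      condition = NA_character_, n_correct = ref_rec$n_correct_counts,
      duration_s = ref_rec$duration_s)
    participants[[j]] <- tibble::tibble(
      participant_id = id, group = grp,
      sigma_mult = sj$sigma_mult, jitter_mult = sj$jitter_mult,
      tau_mult = sj$tau_mult, rate_ref = rate_ref)
    for (cond in sway_conditions) {
      key <- paste(id, "sway", cond, sep = "_")
      sim <- simulate_sway(cfg, grp, cond, duration_s = 30,
                           seed = substream_seed(cfg$seed, id, "sway", cond),
                           participant_id = id, subject = sj)
      trials[[key]] <- sim$trial
      truth[[key]] <- sim$truth
      if (cond_dt(cond)) {
        rec <- simulate_counting(cfg, grp, "sway", 30,
                                 seed = substream_seed(cfg$seed, id,
                                                       "count", cond),
                                 rate_ref = rate_ref)
        counting[[length(counting) + 1L]] <- tibble::tibble(
          participant_id = id, group = grp, context = "sway",
          condition = cond, n_correct = rec$n_correct_counts,
          duration_s = rec$duration_s)
      }
    }
    for (cond in pert_conditions) {
      key <- paste(id, "pert", cond, sep = "_")
      sim <- simulate_perturbation_trial(
        cfg, grp, cond,
        seed = substream_seed(cfg$seed, id, "pert", cond),
        participant_id = id, subject = sj)
      trials[[key]] <- sim$trial
      truth[[key]] <- sim$truth
      if (cond_dt(cond)) {
        dur <- trial_duration(sim$trial)
        rec <- simulate_counting(cfg, grp, "perturbation", dur,
                                 seed = substream_seed(cfg$seed, id,
                                                       "count", "pert", cond),
                                 rate_ref = rate_ref)
        counting[[length(counting) + 1L]] <- tibble::tibble(
          participant_id = id, group = grp, context = "perturbation",
          condition = cond, n_correct = rec$n_correct_counts,
          duration_s = rec$duration_s)
      }
    }
  }
  structure(
    list(trials = trials, truth = truth,
         counting = dplyr::bind_rows(counting),
         participants = dplyr::bind_rows(participants),
         cfg = cfg),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d trials, %d participants (%d PD / %d control), seed %d>\n",
              length(x$trials), nrow(x$participants),
              x$cfg$n_pd, x$cfg$n_control, x$cfg$seed))
  invisible(x)
}

#' Write a synthetic cohort to a directory of CSV files
#'
#' One trial CSV (plus `_events.csv`) per trial via [write_trial()], a
#' `counting.csv` table, and a `truth.json` with per-trial ground truth.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(cohort$trials)) {
    write_trial(cohort$trials[[key]], file.path(dir, paste0(key, ".csv")))
  }
  utils::write.csv(cohort$counting, file.path(dir, "counting.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
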