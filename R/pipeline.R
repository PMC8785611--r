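#' Default analysis parameters
#'
#' Every tunable of the analysis layer in one list, echoed verbatim into
#' outputs for reproducibility: the static analysis window, envelope
#' low-pass, recovery band multiplier and dwell, step-detection thresholds,
#' and the outlier-rule settings.
#'
#' @return Named list of parameters.
#' @export
default_analysis_params <- function() {
  list(
    sway_window_s = c(5, 25),      # middle 20 s of a 30 s trial
    segment_pre_s = 5, segment_post_s = 4.5,
    envelope_lowpass_hz = 10,
    recovery_band_k = 2, recovery_dwell_s = 0.5,
    step_force_threshold_n = 5, step_min_duration_s = 0.05,
    step_merge_gap_s = 0.03, step_min_offset_mm = 20,
    outlier_k = 1.5, outlier_quartile_type = 7,
    mw_exact_max = 16
  )
}

#' Analyze one trial into tidy cohort rows
#'
#' Sway trials yield one row per static outcome (`ellipse_area`,
#' `mean_velocity`). Perturbation trials yield, per event: the dynamic
#' outcomes (`recovery_time`, `cop_max`, `mean_recovery_velocity`), the
#' stepping outcomes (`n_steps`, `step_total_displacement`, plus the
#' strategy label), and the pre-perturbation standing-sway outcomes
#' (`pre_area`, `pre_velocity`). Truncated or otherwise unusable segments
#' are emitted with `discarded = TRUE` and excluded downstream.
#'
#' @param trial A `trial_record`.
#' @param params Analysis parameters, see [default_analysis_params()].
#' @return A tibble: `participant_id`, `group`, `condition`, `trial_kind`,
#'   `ptype`, `event`, `metric`, `value`, `strategy`, `censored`,
#'   `discarded`.
#' @export
analyze_trial <- function(trial, params = default_analysis_params()) {
  stopifnot(inherits(trial, "trial_record"))
  base <- tibble::tibble(
    participant_id = trial$participant_id, group = trial$group,
    condition = trial$condition, trial_kind = trial$trial_kind,
    ptype = NA_character_, event = NA_integer_,
    metric = character(0), value = numeric(0), strategy = NA_character_,
    censored = FALSE, discarded = FALSE
  )
  row <- function(metric, value, ptype = NA_character_,
                  event = NA_integer_, strategy = NA_character_,
                  censored = FALSE, discarded = FALSE) {
    tibble::tibble(
      participant_id = trial$participant_id, group = trial$group,
      condition = trial$condition, trial_kind = trial$trial_kind,
      ptype = ptype, event = event, metric = metric, value = value,
      strategy = strategy, censored = censored, discarded = discarded)
  }
  if (trial$trial_kind == "sway") {
    sm <- sway_metrics(trial, window = params$sway_window_s)
    return(dplyr::bind_rows(
      row("ellipse_area", sm$ellipse_area),
      row("mean_velocity", sm$mean_velocity)
    ))
  }
  out <- list()
  for (i in seq_len(nrow(trial$events))) {
    ev <- trial$events[i, , drop = FALSE]
    seg <- segment_perturbation(trial, ev,
                                pre_s = params$segment_pre_s,
                                post_s = params$segment_post_s,
                                lowpass_hz = params$envelope_lowpass_hz)
    if (seg$discarded) {
      out[[length(out) + 1L]] <- row("recovery_time", NA_real_,
                                     ptype = ev$type, event = i,
                                     discarded = TRUE)
      next
    }
    onset <- ev$onset_s
    steps <- tryCatch(
      detect_steps(trial$left, trial$right,
                   window = c(onset, onset + params$segment_post_s),
                   force_threshold = params$step_force_threshold_n,
                   min_duration_s = params$step_min_duration_s,
                   merge_gap_s = params$step_merge_gap_s,
                   min_offset_mm = params$step_min_offset_mm),
      error = function(e) NULL)
    if (is.null(steps)) {   # signal gap: stepped off the plates
      out[[length(out) + 1L]] <- row("recovery_time", NA_real_,
                                     ptype = ev$type, event = i,
                                     discarded = TRUE)
      next
    }
    sa <- analyze_steps(steps)
    rm_ <- response_metrics(seg, sa, band_k = params$recovery_band_k,
                            dwell_s = params$recovery_dwell_s)
    pre <- pre_perturbation_sway(seg)
    out[[length(out) + 1L]] <- dplyr::bind_rows(
      row("recovery_time", rm_$recovery_time, ev$type, i, sa$strategy,
          censored = rm_$censored),
      row("cop_max", rm_$cop_max, ev$type, i, sa$strategy),
      row("mean_recovery_velocity", rm_$mean_recovery_velocity, ev$type, i,
          sa$strategy),
      row("n_steps", as.numeric(rm_$n_steps), ev$type, i, sa$strategy),
      row("step_total_displacement", rm_$step_total_displacement, ev$type, i,
          sa$strategy),
      row("pre_area", pre$ellipse_area, ev$type, i, sa$strategy),
      row("pre_velocity", pre$mean_velocity, ev$type, i, sa$strategy)
    )
  }
  if (length(out) == 0L) return(base)
  dplyr::bind_rows(out)
}

#' Analyze a set of trials into one cohort table
#'
#' Fail-soft per trial: a trial whose analysis errors is logged and emitted
#' as a single discarded row rather than aborting the cohort.
#'
#' @param trials List of `trial_record`s (e.g. `simulate_cohort()$trials`).
#' @param params Analysis parameters.
#' @return A tidy tibble of per-trial / per-perturbation rows (the cohort
#'   table), with attribute `"discard_log"` listing failed trials.
#' @export
analyze_cohort <- function(trials, params = default_analysis_params()) {
  out <- vector("list", length(trials))
  log <- character(0)
  for (i in seq_along(trials)) {
    key <- if (!is.null(names(trials))) names(trials)[i] else as.character(i)
    res <- tryCatch(analyze_trial(trials[[i]], params),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      log <- c(log, sprintf("%s: %s", key, res))
      tr <- trials[[i]]
      res <- tibble::tibble(
        participant_id = tr$participant_id, group = tr$group,
        condition = tr$condition, trial_kind = tr$trial_kind,
        ptype = NA_character_, event = NA_integer_,
        metric = "trial_failed", value = NA_real_,
        strategy = NA_character_, censored = FALSE, discarded = TRUE)
    }
    out[[i]] <- res
  }
  tbl <- dplyr::bind_rows(out)
  attr(tbl, "discard_log") <- log
  tbl
}

#' Per-participant motor dual-task costs
#'
#' Pairs each participant's NoDT and DT sway outcomes within eyes condition
#' and applies the cost formula `100 * (single - dual) / single`, yielding
#' the four standard rows `dtc_area_EO`, `dtc_area_EC`, `dtc_vel_EO`,
#' `dtc_vel_EC`.
#'
#' @param cohort Cohort table from [analyze_cohort()].
#' @return Tibble: `participant_id`, `group`, `metric`, `value`.
#' @export
derive_dtc <- function(cohort) {
  sway <- dplyr::filter(cohort, .data$trial_kind == "sway", !.data$discarded)
  wide <- tidyr::pivot_wider(
    dplyr::mutate(sway,
                  eyes = cond_eyes(.data$condition),
                  task = ifelse(cond_dt(.data$condition), "dual", "single")),
    id_cols = c("participant_id", "group", "eyes", "metric"),
    names_from = "task", values_from = "value")
  if (!all(c("single", "dual") %in% names(wide))) {
    return(tibble::tibble(participant_id = character(0),
                          group = character(0), metric = character(0),
                          value = numeric(0)))
  }
  ok <- !is.na(wide$single) & !is.na(wide$dual) & wide$single != 0
  wide <- wide[ok, , drop = FALSE]
  short <- c(ellipse_area = "area", mean_velocity = "vel")
  tibble::tibble(
    participant_id = wide$participant_id, group = wide$group,
    metric = paste0("dtc_", short[wide$metric], "_", wide$eyes),
    value = dtc(wide$single, wide$dual))
}

#' Per-participant cognitive dual-task costs from counting records
#'
#' Computes counting rates per context (reference, sway, perturbation;
#' multiple records per context are pooled: total counts over total time)
#' and the three costs `cdtc_sway`, `cdtc_pert`, `cdtc_sway_vs_pert`, plus
#' the rates themselves (`cr_reference`, `cr_sway`, `cr_pert`).
#'
#' @param counting Tibble with columns `participant_id`, `group`,
#'   `context`, `n_correct`, `duration_s` (as in
#'   `simulate_cohort()$counting`).
#' @return Tibble: `participant_id`, `group`, `metric`, `value`.
#' @export
derive_cognitive_dtc <- function(counting) {
  rates <- counting |>
    dplyr::group_by(.data$participant_id, .data$group, .data$context) |>
    dplyr::summarise(rate = 60 * sum(.data$n_correct) / sum(.data$duration_s),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "context", values_from = "rate")
  for (col in c("reference", "sway", "perturbation")) {
    if (!col %in% names(rates)) rates[[col]] <- NA_real_
  }
  out <- list()
  add <- function(metric, value) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      participant_id = rates$participant_id, group = rates$group,
      metric = metric, value = value)
  }
  add("cr_reference", rates$reference)
  add("cr_sway", rates$sway)
  add("cr_pert", rates$perturbation)
  safe_cdtc <- function(a, b) ifelse(!is.na(a) & a != 0 & !is.na(b),
                                     100 * (a - b) / a, NA_real_)
  add("cdtc_sway", safe_cdtc(rates$reference, rates$sway))
  add("cdtc_pert", safe_cdtc(rates$reference, rates$perturbation))
  add("cdtc_sway_vs_pert", safe_cdtc(rates$sway, rates$perturbation))
  dplyr::filter(dplyr::bind_rows(out), !is.na(.data$value))
}

participant_metric_table <- function(cohort) {
  ok <- dplyr::filter(cohort, !.data$discarded, !is.na(.data$value))
  sway <- ok |>
    dplyr::filter(.data$trial_kind == "sway") |>
    dplyr::group_by(.data$participant_id, .data$group,
                    metric = paste0(.data$metric, "_",
                                    sub("_NoDT", "", sub("_DT", "_DT",
                                                         .data$condition)))) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  pert <- ok |>
    dplyr::filter(.data$trial_kind == "perturbation",
                  .data$metric %in% c("recovery_time", "cop_max",
                                      "mean_recovery_velocity",
                                      "pre_area", "pre_velocity",
                                      "step_total_displacement"))
  in_place <- pert |>
    dplyr::filter(.data$strategy == "in_place",
                  .data$metric %in% c("recovery_time", "cop_max",
                                      "mean_recovery_velocity")) |>
    dplyr::group_by(.data$participant_id, .data$group,
                    metric = paste0("inplace_", .data$metric)) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  stepping <- pert |>
    dplyr::filter(.data$strategy != "in_place",
                  .data$metric %in% c("recovery_time",
                                      "step_total_displacement")) |>
    dplyr::group_by(.data$participant_id, .data$group,
                    metric = paste0("step_", .data$metric)) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  prior <- pert |>
    dplyr::filter(.data$metric %in% c("pre_area", "pre_velocity")) |>
    dplyr::group_by(.data$participant_id, .data$group, metric = .data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  step_rate <- ok |>
    dplyr::filter(.data$trial_kind == "perturbation",
                  .data$metric == "recovery_time") |>
    dplyr::group_by(.data$participant_id, .data$group) |>
    dplyr::summarise(value = 100 * mean(.data$strategy != "in_place"),
                     .groups = "drop") |>
    dplyr::mutate(metric = "step_response_pct")
  dplyr::bind_rows(sway, in_place, stepping, prior, step_rate)
}

#' Assemble the group-comparison report
#'
#' Builds the per-participant summary metrics (sway outcomes per condition,
#' pooled in-place and stepping perturbation outcomes, pre-perturbation
#' standing sway, step-response percentage, dual-task costs), then compares
#' groups metric-wise: single-pass IQR outlier removal per group followed
#' by a two-sided Mann-Whitney test. Multiple-step episodes are compared as
#' a 2x2 participant table (any multiple-step episode vs none, among
#' participants with at least one step response), reporting the plain
#' chi-squared alongside Yates and Fisher p-values. No multiple-testing
#' correction is applied to the primary p-values; a Benjamini-Hochberg
#' column is emitted for transparency.
#'
#' @param cohort Cohort table from [analyze_cohort()].
#' @param counting Optional counting tibble for the cognitive costs.
#' @param params Analysis parameters.
#' @return A `balance_report` list: `summary` (tibble, one row per metric),
#'   `multiple_steps` (counts + tests), `per_type` (per-perturbation-type
#'   recovery-time comparisons), `participant_metrics`, `discard_rate`,
#'   `params`.
#' @export
build_report <- function(cohort, counting = NULL,
                         params = default_analysis_params()) {
  pm <- participant_metric_table(cohort)
  if (!is.null(counting)) {
    pm <- dplyr::bind_rows(pm, derive_dtc(cohort),
                           derive_cognitive_dtc(counting))
  } else {
    pm <- dplyr::bind_rows(pm, derive_dtc(cohort))
  }
  rows <- list()
  for (m in unique(pm$metric)) {
    sub <- dplyr::filter(pm, .data$metric == m)
    a <- sub$value[sub$group == "PD"]
    b <- sub$value[sub$group == "control"]
    if (length(a) < 3L || length(b) < 3L) {
      warning("build_report: metric ", m, " missing for a group; row is n/a")
      rows[[m]] <- tibble::tibble(
        metric = m, n_pd = length(a), n_control = length(b),
        mean_pd = NA_real_, sd_pd = NA_real_, mean_control = NA_real_,
        sd_control = NA_real_, outliers_pd = NA_integer_,
        outliers_control = NA_integer_, U = NA_real_, p = NA_real_,
        method = NA_character_)
      next
    }
    cmp <- suppressWarnings(
      compare_groups(a, b, k = params$outlier_k,
                     exact_max = params$mw_exact_max))
    rows[[m]] <- tibble::tibble(
      metric = m, n_pd = cmp$n[["a"]], n_control = cmp$n[["b"]],
      mean_pd = cmp$mean_sd$a[["mean"]], sd_pd = cmp$mean_sd$a[["sd"]],
      mean_control = cmp$mean_sd$b[["mean"]],
      sd_control = cmp$mean_sd$b[["sd"]],
      outliers_pd = cmp$outliers_removed[["a"]],
      outliers_control = cmp$outliers_removed[["b"]],
      U = cmp$U, p = cmp$p_two_sided, method = cmp$method)
  }
  summary_tbl <- dplyr::bind_rows(rows)
  summary_tbl$p_bh <- stats::p.adjust(summary_tbl$p, method = "BH")
  # multiple-step episodes among steppers: 2x2 participants table
  strat <- cohort |>
    dplyr::filter(.data$trial_kind == "perturbation", !.data$discarded,
                  .data$metric == "recovery_time") |>
    dplyr::group_by(.data$participant_id, .data$group) |>
    dplyr::summarise(
      any_step = any(.data$strategy != "in_place"),
      any_multi = any(.data$strategy == "multiple_steps"),
      .groups = "drop") |>
    dplyr::filter(.data$any_step)
  ms <- NULL
  if (nrow(strat) > 0L) {
    tab <- with(strat, table(
      factor(group, c("PD", "control")),
      factor(ifelse(any_multi, "multi", "no_multi"), c("multi", "no_multi"))))
    ms <- list(table = unclass(tab))
    ms$tests <- tryCatch(categorical_2x2(tab), error = function(e) NULL)
  }
  per_type <- cohort |>
    dplyr::filter(.data$trial_kind == "perturbation", !.data$discarded,
                  .data$metric == "recovery_time") |>
    dplyr::group_by(.data$ptype, .data$group) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  pert_rows <- dplyr::filter(cohort, .data$trial_kind == "perturbation",
                             .data$metric %in% c("recovery_time",
                                                 "trial_failed"))
  discard_rate <- if (nrow(pert_rows)) mean(pert_rows$discarded) else NA_real_
  structure(
    list(summary = summary_tbl, multiple_steps = ms, per_type = per_type,
         participant_metrics = pm, discard_rate = discard_rate,
         params = params),
    class = "balance_report"
  )
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance_report: %d metrics, discard rate %.1f%%>\n",
              nrow(x$summary), 100 * x$discard_rate))
  print(as.data.frame(x$summary), digits = 3)
  invisible(x)
}

#' Write a report to CSV, JSON and markdown
#'
#' @param report A `balance_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "balance_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summary, file.path(dir, "report_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$participant_metrics,
                   file.path(dir, "participant_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(summary = report$summary, multiple_steps = report$multiple_steps,
         per_type = report$per_type, discard_rate = report$discard_rate,
         params = report$params),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)
  md <- c("# Group comparison report", "",
          sprintf("Perturbation discard rate: %.1f%%",
                  100 * report$discard_rate), "",
          "| metric | PD mean±SD | control mean±SD | outliers (PD/ctrl) | U | p |",
          "|---|---|---|---|---|---|",
          sprintf("| %s | %.3g ± %.3g | %.3g ± %.3g | %d/%d | %g | %.4g |",
                  report$summary$metric, report$summary$mean_pd,
                  report$summary$sd_pd, report$summary$mean_control,
                  report$summary$sd_control, report$summary$outliers_pd,
                  report$summary$outliers_control, report$summary$U,
                  report$summary$p))
  if (!is.null(report$multiple_steps) && !is.null(report$multiple_steps$tests)) {
    ms <- report$multiple_steps
    md <- c(md, "",
            sprintf("Multiple-step episodes (PD %d/%d vs control %d/%d): chi-squared %.4g (p = %.4g), Yates p = %.4g, Fisher p = %.4g",
                    ms$table[1, 1], sum(ms$table[1, ]), ms$table[2, 1],
                    sum(ms$table[2, ]), ms$tests$chisq, ms$tests$p_chisq,
                    ms$tests$p_yates, ms$tests$p_fisher))
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' Run the full file-based analysis
#'
#' Reads every trial CSV in `input_dir` (files matching `*.csv`, excluding
#' `*_events.csv`, `counting.csv` and `truth.json` companions), analyzes
#' each trial fail-soft, assembles the cohort table and the group report,
#' and writes `cohort.csv`, `report_summary.csv`, `report.json`,
#' `report.md` and a `run_params.json` echo into `out_dir`. Deterministic
#' given inputs and parameters.
#'
#' @param input_dir Directory of trial CSVs (e.g. from [write_cohort()]).
#' @param out_dir Output directory.
#' @param params Analysis parameters.
#' @return The `balance_report`, invisibly; the cohort table is attached as
#'   attribute `"cohort"`.
#' @export
run_analysis <- function(input_dir, out_dir,
                         params = default_analysis_params()) {
  if (!dir.exists(input_dir)) {
    stop("run_analysis: no such input directory: ", input_dir, call. = FALSE)
  }
  files <- list.files(input_dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[!grepl("_events\\.csv$|(^|/)counting\\.csv$", files)]
  if (length(files) == 0L) {
    stop("run_analysis: no trial files in ", input_dir, call. = FALSE)
  }
  trials <- list()
  read_log <- character(0)
  for (f in files) {
    tr <- tryCatch(read_trial(f), error = function(e) conditionMessage(e))
    if (is.character(tr)) {
      read_log <- c(read_log, sprintf("%s: %s", basename(f), tr))
    } else {
      trials[[sub("\\.csv$", "", basename(f))]] <- tr
    }
  }
  if (length(trials) == 0L) {
    stop("run_analysis: no readable trials in ", input_dir, call. = FALSE)
  }
  cohort <- analyze_cohort(trials, params)
  counting_path <- file.path(input_dir, "counting.csv")
  counting <- if (file.exists(counting_path)) {
    tibble::as_tibble(utils::read.csv(counting_path,
                                      stringsAsFactors = FALSE))
  } else NULL
  report <- build_report(cohort, counting, params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  write_report(report, out_dir)
  jsonlite::write_json(
    list(params = params, n_trials = length(trials),
         unreadable_trials = read_log,
         discard_log = attr(cohort, "discard_log")),
    file.path(out_dir, "run_params.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(read_log)) {
    message("run_analysis: ", length(read_log),
            " unreadable trial(s) skipped; see run_params.json")
  }
  attr(report, "cohort") <- cohort
  invisible(report)
}
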