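#' Construct a trial record
#'
#' One balance trial: two plate signals plus metadata, the perturbation
#' event list (empty for quiet-stance trials), and an optional counting
#' record for dual-task trials.
#'
#' @param participant_id Participant identifier.
#' @param group "PD" or "control".
#' @param condition One of "EO_NoDT", "EO_DT", "EC_NoDT", "EC_DT".
#' @param trial_kind "sway" or "perturbation".
#' @param left,right `plate_signal` objects.
#' @param events Data frame with columns `onset_s`, `type` (may be empty).
#' @param counting Optional `counting_record`.
#' @return A `trial_record`.
#' @export
trial_record <- function(participant_id, group, condition, trial_kind,
                         left, right, events = empty_events(),
                         counting = NULL) {
  group <- match.arg(group, c("PD", "control"))
  condition <- match.arg(condition, c("EO_NoDT", "EO_DT", "EC_NoDT", "EC_DT"))
  trial_kind <- match.arg(trial_kind, c("sway", "perturbation"))
  stopifnot(inherits(left, "plate_signal"), inherits(right, "plate_signal"))
  if (length(left$fz) != length(right$fz)) {
    stop("trial_record: plates differ in length", call. = FALSE)
  }
  events <- validate_events(events)
  if (trial_kind == "sway" && length(left$fz) / left$fs < 30 - 1e-9) {
    stop("trial_record: sway trials must span at least 30 s", call. = FALSE)
  }
  if (nrow(events) > 1L && any(diff(events$onset_s) <= 0)) {
    stop("trial_record: events must be sorted by onset", call. = FALSE)
  }
  structure(
    list(participant_id = as.character(participant_id), group = group,
         condition = condition, trial_kind = trial_kind,
         left = left, right = right, events = events, counting = counting),
    class = "trial_record"
  )
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record %s/%s %s %s: %.1f s @ %g Hz, %d event(s)>\n",
              x$participant_id, x$group, x$condition, x$trial_kind,
              length(x$left$fz) / x$left$fs, x$left$fs, nrow(x$events)))
  invisible(x)
}

#' Trial duration in seconds
#' @param trial A `trial_record`.
#' @export
trial_duration <- function(trial) length(trial$left$fz) / trial$left$fs

perturbation_types <- function() {
  as.vector(outer(c("trans", "tilt"), c("fwd", "bwd", "left", "right"),
                  paste, sep = "_"))
}

empty_events <- function() {
  data.frame(onset_s = numeric(0), type = character(0),
             stringsAsFactors = FALSE)
}

validate_events <- function(events) {
  if (is.null(events)) return(empty_events())
  events <- as.data.frame(events)
  if (nrow(events) == 0L) return(empty_events())
  if (!all(c("onset_s", "type") %in% names(events))) {
    stop("events need columns onset_s, type", call. = FALSE)
  }
  bad <- setdiff(unique(events$type), perturbation_types())
  if (length(bad)) {
    stop("unknown perturbation type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  events[order(events$onset_s), c("onset_s", "type"), drop = FALSE]
}

#' Read one trial from its CSV pair
#'
#' Trial files carry `# key=value` header lines (`fs_hz`, `participant`,
#' `group`, `condition`, `kind`) followed by columns
#' `t,fz_L,copx_L,copy_L,fz_R,copx_R,copy_R` (s, N, mm). The companion
#' event file (columns `onset_s,type`) is read when present.
#'
#' @param path Trial CSV path.
#' @param events_path Event CSV path, or `NULL` to look for
#'   `<path stem>_events.csv` and fall back to no events.
#' @return A validated `trial_record`.
#' @export
read_trial <- function(path, events_path = NULL) {
  if (!file.exists(path)) stop("read_trial: no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) == 0L || any(diff(hdr_idx) != 1L) || hdr_idx[1L] != 1L) {
    stop("read_trial: malformed header in ", path, call. = FALSE)
  }
  meta <- list()
  for (h in lines[hdr_idx]) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("read_trial: malformed header line: ", h, call. = FALSE)
    meta[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  need <- c("fs_hz", "participant", "group", "condition", "kind")
  if (!all(need %in% names(meta))) {
    stop("read_trial: header missing ",
         paste(setdiff(need, names(meta)), collapse = ", "), call. = FALSE)
  }
  fs <- suppressWarnings(as.numeric(meta$fs_hz))
  if (!is.finite(fs) || fs <= 0) stop("read_trial: bad fs_hz header", call. = FALSE)
  df <- utils::read.csv(text = lines[-hdr_idx], stringsAsFactors = FALSE)
  cols <- c("t", "fz_L", "copx_L", "copy_L", "fz_R", "copx_R", "copy_R")
  if (!identical(names(df), cols)) {
    stop("read_trial: expected columns ", paste(cols, collapse = ","),
         " in ", path, call. = FALSE)
  }
  if (anyNA(df$t) || anyNA(df$fz_L) || anyNA(df$fz_R)) {
    stop("read_trial: ragged or non-numeric row ",
         which(is.na(df$t) | is.na(df$fz_L) | is.na(df$fz_R))[1L],
         " in ", path, call. = FALSE)
  }
  if (any(diff(df$t) <= 0)) {
    stop("read_trial: non-monotonic time column at row ",
         which(diff(df$t) <= 0)[1L] + 1L, call. = FALSE)
  }
  if (any(df$fz_L < 0)) {
    stop("read_trial: negative fz_L at row ", which(df$fz_L < 0)[1L],
         call. = FALSE)
  }
  if (any(df$fz_R < 0)) {
    stop("read_trial: negative fz_R at row ", which(df$fz_R < 0)[1L],
         call. = FALSE)
  }
  if (is.null(events_path)) {
    candidate <- paste0(sub("\\.csv$", "", path), "_events.csv")
    events_path <- if (file.exists(candidate)) candidate else NA
  }
  events <- if (is.character(events_path) && !is.na(events_path)) {
    utils::read.csv(events_path, stringsAsFactors = FALSE)
  } else {
    empty_events()
  }
  trial_record(
    participant_id = meta$participant, group = meta$group,
    condition = meta$condition, trial_kind = meta$kind,
    left = plate_signal("left", df$fz_L, df$copx_L, df$copy_L, fs),
    right = plate_signal("right", df$fz_R, df$copx_R, df$copy_R, fs),
    events = events
  )
}

#' Write one trial (and its events) to CSV
#'
#' Inverse of [read_trial()]: `read_trial(write_trial(trial, path))`
#' reproduces the trial up to float formatting precision.
#'
#' @param trial A `trial_record`.
#' @param path Output CSV path; events go to `<stem>_events.csv` when the
#'   trial has any.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial_record"))
  n <- length(trial$left$fz)
  t <- (seq_len(n) - 1L) / trial$left$fs
  df <- data.frame(
    t = t,
    fz_L = trial$left$fz, copx_L = trial$left$cop_x, copy_L = trial$left$cop_y,
    fz_R = trial$right$fz, copx_R = trial$right$cop_x, copy_R = trial$right$cop_y
  )
  hdr <- c(
    sprintf("# fs_hz=%.10g", trial$left$fs),
    sprintf("# participant=%s", trial$participant_id),
    sprintf("# group=%s", trial$group),
    sprintf("# condition=%s", trial$condition),
    sprintf("# kind=%s", trial$trial_kind)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  if (nrow(trial$events) > 0L) {
    utils::write.csv(trial$events,
                     paste0(sub("\\.csv$", "", path), "_events.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
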