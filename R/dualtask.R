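#' Dual-task cost of a balance metric
#'
#' `DTC = 100 * (single - dual) / single` (percent). Negative when the
#' dual-task value is larger than the single-task value — the usual case
#' for sway area and velocity, which inflate under a concurrent cognitive
#' load.
#'
#' @param single Single-task score (nonzero).
#' @param dual Dual-task score.
#' @return Cost in percent.
#' @export
dtc <- function(single, dual) {
  if (any(single == 0)) stop("dtc: single-task score is zero", call. = FALSE)
  100 * (single - dual) / single
}

#' Construct a counting-task record
#'
#' Tally of correct serial-subtraction responses over a timed context
#' (baseline reference, quiet-stance sway, or the perturbation trial).
#'
#' @param n_correct_counts Number of correct counts (non-negative integer).
#' @param duration_s Context duration (s, positive).
#' @param context "reference", "sway" or "perturbation".
#' @return A `counting_record`.
#' @export
counting_record <- function(n_correct_counts, duration_s, context) {
  context <- match.arg(context, c("reference", "sway", "perturbation"))
  if (n_correct_counts < 0) stop("counting_record: negative count", call. = FALSE)
  if (duration_s <= 0) stop("counting_record: non-positive duration", call. = FALSE)
  structure(list(n_correct_counts = as.integer(round(n_correct_counts)),
                 duration_s = as.numeric(duration_s), context = context),
            class = "counting_record")
}

#' Counting rate in counts per minute
#'
#' @param rec A `counting_record`.
#' @return `60 * n_correct_counts / duration_s` (counts/min).
#' @export
counting_rate <- function(rec) {
  stopifnot(inherits(rec, "counting_record"))
  60 * rec$n_correct_counts / rec$duration_s
}

#' Cognitive dual-task cost between two counting rates
#'
#' `C-DTC = 100 * (cr_a - cr_b) / cr_a`, applied as (reference, sway),
#' (reference, perturbation) and (sway, perturbation) for the three
#' reported costs. The three are algebraically linked: with
#' `s = cdtc(ref, sway)` and `p = cdtc(ref, pert)`,
#' `cdtc(sway, pert) = 100 * (p - s) / (100 - s)`.
#'
#' @param cr_a Baseline rate for the cost (counts/min, nonzero).
#' @param cr_b Comparison rate (counts/min).
#' @return Cost in percent.
#' @export
cognitive_dtc <- function(cr_a, cr_b) {
  if (any(cr_a == 0)) stop("cognitive_dtc: baseline rate is zero", call. = FALSE)
  100 * (cr_a - cr_b) / cr_a
}
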