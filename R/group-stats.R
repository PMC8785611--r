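#' Single-pass interquartile-range outlier removal
#'
#' Keeps `v` iff `|v - median| <= 1.5 * IQR`, with quartiles computed by
#' linear interpolation (`stats::quantile` type 7). Applied once, never
#' iterated: re-application to the kept set may remove further points and
#' is deliberately not performed. With fewer than 4 values no removal is
#' attempted (a quartile on 3 points is not meaningful) and a warning is
#' issued.
#'
#' @param values Numeric vector.
#' @param k Multiplier on the IQR (default 1.5).
#' @param quartile_type `stats::quantile` type (default 7, linear
#'   interpolation).
#' @return List: `kept`, `removed`, `kept_idx`, `n_removed`.
#' @export
remove_outliers <- function(values, k = 1.5, quartile_type = 7) {
  values <- as.numeric(values)
  if (length(values) < 4L) {
    warning("remove_outliers: fewer than 4 values, no removal attempted")
    return(list(kept = values, removed = numeric(0),
                kept_idx = seq_along(values), n_removed = 0L))
  }
  med <- stats::median(values)
  q <- stats::quantile(values, c(0.25, 0.75), type = quartile_type,
                       names = FALSE)
  iqr <- q[2L] - q[1L]
  keep <- abs(values - med) <= k * iqr + 1e-12
  list(kept = values[keep], removed = values[!keep],
       kept_idx = which(keep), n_removed = sum(!keep))
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test via
#' [stats::wilcox.test()]: the exact null distribution when the combined
#' sample is small (`n1 + n2 <= exact_max`) and tie-free, a tie-corrected
#' normal approximation (without continuity correction) otherwise. The
#' method actually used is recorded in the result.
#'
#' @param a,b Numeric vectors (each of length >= 3).
#' @param exact_max Largest combined sample size for the exact test
#'   (default 16).
#' @return A `comparison_result`: `U` (for group a), `p_two_sided`,
#'   `method` ("exact" or "normal_approx"), `n` (per group), `mean_sd`
#'   (per group), plus empty outlier bookkeeping fields.
#' @export
mann_whitney <- function(a, b, exact_max = 16) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L) {
    stop("mann_whitney: each group needs at least 3 values", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- !ties && (length(a) + length(b)) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = FALSE)
  )
  structure(
    list(U = unname(wt$statistic), p_two_sided = wt$p.value,
         method = if (use_exact) "exact" else "normal_approx",
         n = c(a = length(a), b = length(b)),
         mean_sd = list(a = c(mean = mean(a), sd = stats::sd(a)),
                        b = c(mean = mean(b), sd = stats::sd(b))),
         outliers_removed = c(a = 0L, b = 0L)),
    class = "comparison_result"
  )
}

#' Outlier-filtered Mann-Whitney comparison
#'
#' Applies [remove_outliers()] once per group, then [mann_whitney()] on the
#' kept values; per-group removal counts are carried into the result, as in
#' a report table footnote.
#'
#' @inheritParams mann_whitney
#' @inheritParams remove_outliers
#' @return A `comparison_result` with `outliers_removed` filled in.
#' @export
compare_groups <- function(a, b, k = 1.5, exact_max = 16) {
  oa <- remove_outliers(a, k = k)
  ob <- remove_outliers(b, k = k)
  res <- mann_whitney(oa$kept, ob$kept, exact_max = exact_max)
  res$outliers_removed <- c(a = oa$n_removed, b = ob$n_removed)
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison: U = %g, p = %.4g (%s), n = %d vs %d, outliers removed %d/%d>\n",
    x$U, x$p_two_sided, x$method, x$n[1L], x$n[2L],
    x$outliers_removed[1L], x$outliers_removed[2L]))
  invisible(x)
}

#' Association tests on a 2x2 contingency table
#'
#' Reports the plain (uncorrected) chi-squared statistic and p-value, the
#' Yates-corrected p, and the Fisher exact p side by side: on very small
#' tables the three can disagree substantially, so all are emitted and the
#' caller chooses.
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @return List: `chisq` (uncorrected statistic), `p_chisq`, `p_yates`,
#'   `p_fisher`, `expected` (matrix of expected counts).
#' @export
categorical_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) {
    stop("categorical_2x2: need a 2x2 table", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("categorical_2x2: counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("categorical_2x2: zero margin, association undefined", call. = FALSE)
  }
  plain <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  yates <- suppressWarnings(stats::chisq.test(counts, correct = TRUE))
  fish <- stats::fisher.test(counts)
  list(chisq = unname(plain$statistic), p_chisq = plain$p.value,
       p_yates = yates$p.value, p_fisher = fish$p.value,
       expected = plain$expected)
}
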