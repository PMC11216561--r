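# Sample moments and one-sample normality diagnostics.
#
# Conventions (chosen to match the reference cohort table, where kurtosis
# values sit near 3-8 and the text reads "leptokurtic (kurtosis > 3)"):
#   * kurtosis is NON-excess: m4/m2^2, normal = 3;
#   * skew and kurtosis use n-denominator central moments;
#   * sd uses the usual n-1 denominator;
#   * quartiles use linear interpolation (quantile type 7).

central_moment <- function(x, k) mean((x - mean(x))^k)

#' Sample moments of a prediction distribution
#'
#' @param samples Numeric vector, n >= 3.
#' @return Tibble with one row: `n`, `mean`, `median`, `sd` (n-1), `skew`
#'   (m3/m2^1.5), `kurtosis` (m4/m2^2, non-excess), `iqr`, `min`, `max`,
#'   `range`. For a zero-variance sample, `skew` and `kurtosis` are `NA`.
#' @export
sample_moments <- function(samples) {
  x <- as.numeric(samples)
  if (length(x) < 3L)
    stop_icpdx("validation_error", "need at least 3 samples for moment estimates.")
  if (!all(is.finite(x)))
    stop_icpdx("validation_error", "samples must all be finite.")
  m2 <- central_moment(x, 2)
  if (m2 == 0) {
    skew <- NA_real_; kurt <- NA_real_
  } else {
    skew <- central_moment(x, 3) / m2^1.5
    kurt <- central_moment(x, 4) / m2^2
  }
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  tibble::tibble(
    n = length(x), mean = mean(x), median = stats::median(x),
    sd = stats::sd(x), skew = skew, kurtosis = kurt,
    iqr = q[2] - q[1], min = min(x), max = max(x), range = max(x) - min(x)
  )
}

standardize_sorted <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L)
    stop_icpdx("validation_error", "need at least 3 samples.")
  s <- stats::sd(x)
  if (s == 0)
    stop_icpdx("degenerate_error", "zero-variance sample: normality statistic undefined.")
  sort((x - mean(x)) / s)
}

#' Lilliefors one-sample Kolmogorov-Smirnov statistic
#'
#' Supremum distance between the sample ECDF and the normal CDF with mean
#' and sd estimated from the sample (the Lilliefors form):
#' `D = max_i max(|i/n - Phi(z_(i))|, |(i-1)/n - Phi(z_(i))|)`.
#' Only the statistic is returned -- it is used here as a graded measure of
#' departure from normality of the distribution body, not as a test.
#'
#' @param samples Numeric vector, n >= 3, nonzero variance.
#' @return The statistic `D` in (0, 1).
#' @export
lilliefors_ks <- function(samples) {
  z <- standardize_sorted(samples)
  n <- length(z)
  p <- stats::pnorm(z)
  max(pmax(abs(seq_len(n) / n - p), abs((seq_len(n) - 1) / n - p)))
}

#' Anderson-Darling normality statistic
#'
#' `A^2 = -n - (1/n) * sum_i (2i-1) [ln Phi(z_(i)) + ln(1 - Phi(z_(n+1-i)))]`
#' with parameters estimated from the sample. Tail-weighted counterpart of
#' [lilliefors_ks()]. No small-sample correction factor is applied, so
#' values are directly comparable across the very different per-case sample
#' sizes of a cohort.
#'
#' @param samples Numeric vector, n >= 3, nonzero variance.
#' @return The statistic `A^2` (>= 0 up to numerical tolerance).
#' @export
anderson_darling <- function(samples) {
  z <- standardize_sorted(samples)
  n <- length(z)
  # log of the lower/upper normal tail via the log.p path: numerically safe
  # where pnorm() underflows to 0 or rounds to 1.
  log_lo <- stats::pnorm(z, log.p = TRUE)
  log_up <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
  i <- seq_len(n)
  -n - sum((2 * i - 1) * (log_lo + rev(log_up))) / n
}

#' Prediction error Diff_ICPmd
#'
#' Absolute difference between the lumbar-puncture measured ICP and the
#' median of the predicted ICP distribution, cm water.
#'
#' @param measured_icp Measured ICP, cm water.
#' @param predicted_median Median of the predicted distribution, cm water.
#' @return `|measured_icp - predicted_median|`.
#' @export
diff_icp_md <- function(measured_icp, predicted_median) {
  if (!all(is.finite(measured_icp)) || !all(is.finite(predicted_median)))
    stop_icpdx("validation_error", "both arguments must be finite.")
  abs(measured_icp - predicted_median)
}
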