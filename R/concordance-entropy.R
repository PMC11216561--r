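# Arterial/venous concordance (two-sample Kolmogorov-Smirnov) and Shannon
# entropy of the binned prediction distribution.
#
# Within one case the arterial and venous models predict ICP independently;
# if both are trustworthy their predictive distributions should agree. The
# two-sample KS statistic (tsKS) quantifies the maximal ECDF gap between
# them. Shannon entropy quantifies how uninformative a single distribution
# is: it is maximal for a uniform (random) prediction.

#' Evaluate an empirical CDF
#'
#' Right-continuous step function: the fraction of samples `<= x`.
#'
#' @param samples Numeric vector, n >= 1.
#' @param x Evaluation points.
#' @return Probabilities in `[0, 1]`.
#' @export
ecdf_eval <- function(samples, x) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop_icpdx("validation_error", "need at least 1 sample for an ECDF.")
  stats::ecdf(samples)(x)
}

# Asymptotic Kolmogorov survival function Q(lambda) = 2 sum (-1)^(k-1)
# exp(-2 k^2 lambda^2), truncated when terms drop below 1e-10.
kolmogorov_q <- function(lambda) {
  if (lambda <= 0) return(1)
  total <- 0
  for (k in 1:200) {
    term <- 2 * (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
    total <- total + term
    if (abs(term) < 1e-10) break
  }
  min(max(total, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov concordance
#'
#' The tsKS statistic between two prediction samples (typically one case's
#' arterial and venous predictions): the supremum over all pooled sample
#' points of the absolute ECDF difference. The asymptotic p-value uses the
#' effective sample size `n_eff = n1 * n2 / (n1 + n2)` -- the product of
#' the distribution data-point counts divided by their sum -- with
#' `lambda = (sqrt(n_eff) + 0.12 + 0.11/sqrt(n_eff)) * D`.
#'
#' @param samples1,samples2 Numeric vectors, each n >= 1.
#' @return A list of class `icpdx_concordance`: `d_stat`, `p_value`,
#'   `x_at_max` (smallest pooled point achieving the supremum, cm water),
#'   `n1`, `n2`, `n_eff`.
#' @export
two_sample_ks <- function(samples1, samples2) {
  s1 <- as.numeric(samples1); s2 <- as.numeric(samples2)
  if (length(s1) < 1L || length(s2) < 1L)
    stop_icpdx("validation_error", "both samples must be non-empty.")
  pooled <- sort(unique(c(s1, s2)))
  gap <- abs(ecdf_eval(s1, pooled) - ecdf_eval(s2, pooled))
  d <- max(gap)
  x_at_max <- pooled[which.max(gap)]   # which.max takes the first (smallest) point
  n1 <- length(s1); n2 <- length(s2)
  n_eff <- n1 * n2 / (n1 + n2)
  p <- if (d == 0) 1 else
    kolmogorov_q((sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * d)
  structure(
    list(d_stat = d, p_value = p, x_at_max = x_at_max,
         n1 = n1, n2 = n2, n_eff = n_eff),
    class = "icpdx_concordance"
  )
}

#' @export
print.icpdx_concordance <- function(x, ...) {
  cat(sprintf("<icpdx_concordance> D = %.5f at x = %.2f cm water (n1 = %d, n2 = %d, p = %.3g)\n",
              x$d_stat, x$x_at_max, x$n1, x$n2, x$p_value))
  invisible(x)
}

#' Shannon entropy of a binned prediction distribution
#'
#' Plug-in estimate `H = -sum_b P(b) log2 P(b)` (bits) over `n_bins`
#' equal-width bins spanning the sample range, the last bin right-closed;
#' `0 * log2(0)` is taken as 0. Entropy is maximal, `log2(n_bins)`, for
#' equal bin occupancy -- the signature of a prediction distribution that
#' has degenerated toward uniform.
#'
#' @param samples Numeric vector, n >= 1.
#' @param n_bins Number of bins (>= 2; default 64).
#' @return A list of class `icpdx_entropy`: `sent` (bits), `n_bins`,
#'   `bin_probabilities`.
#' @export
shannon_entropy <- function(samples, n_bins = 64L) {
  x <- as.numeric(samples)
  if (length(x) < 1L)
    stop_icpdx("validation_error", "need at least 1 sample for entropy.")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L)
    stop_icpdx("argument_error", "`n_bins` must be >= 2.")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    rlang::warn("constant sample: all mass in a single bin, entropy = 0.")
    p <- c(1, rep(0, n_bins - 1L))
  } else {
    width <- diff(rng) / n_bins
    idx <- pmin(floor((x - rng[1]) / width) + 1L, n_bins)
    p <- tabulate(idx, nbins = n_bins) / length(x)
  }
  nz <- p > 0
  h <- -sum(p[nz] * log2(p[nz]))
  structure(list(sent = h, n_bins = n_bins, bin_probabilities = p),
            class = "icpdx_entropy")
}

#' @export
print.icpdx_entropy <- function(x, ...) {
  cat(sprintf("<icpdx_entropy> H = %.4f bits over %d bins (max %.2f)\n",
              x$sent, x$n_bins, log2(x$n_bins)))
  invisible(x)
}

#' Paired ECDF export for one case
#'
#' @param arterial,venous Numeric prediction samples.
#' @param grid_size Number of evaluation points spanning the pooled range.
#' @return Tibble `x`, `ecdf_arterial`, `ecdf_venous`.
#' @export
ecdf_pair_to_tibble <- function(arterial, venous, grid_size = 512L) {
  rng <- range(c(arterial, venous))
  x <- seq(rng[1], rng[2], length.out = grid_size)
  tibble::tibble(x = x,
                 ecdf_arterial = ecdf_eval(arterial, x),
                 ecdf_venous = ecdf_eval(venous, x))
}
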